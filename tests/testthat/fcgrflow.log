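2026-09-28T19:53:05  cmd=evaluate acceptance  config_hash=5996b35337e41f4669087ecbb44869dc  seed=2 
2026-09-28T19:55:16  cmd=evaluate acceptance  config_hash=5996b35337e41f4669087ecbb44869dc  seed=2 
2026-09-28T20:05:43  cmd=evaluate acceptance  config_hash=5996b35337e41f4669087ecbb44869dc  seed=2 
2026-09-28T20:24:11  cmd=evaluate acceptance  config_hash=5996b35337e41f4669087ecbb44869dc  seed=2 
2026-09-28T20:26:52  cmd=evaluate acceptance  config_hash=5996b35337e41f4669087ecbb44869dc  seed=2 
2026-09-28T20:28:57  cmd=evaluate acceptance  config_hash=5996b35337e41f4669087ecbb44869dc  seed=2 
2026-09-28T20:42:10  cmd=evaluate acceptance  config_hash=5996b35337e41f4669087ecbb44869dc  seed=2 
2026-09-28T20:47:05  cmd=evaluate acceptance  config_hash=5996b35337e41f4669087ecbb44869dc  seed=2 
2026-09-28T20:48:22  cmd=evaluate acceptance  config_hash=5996b35337e41f4669087ecbb44869dc  seed=2 
2026-09-28T20:50:42  cmd=evaluate acceptance  config_hash=5996b35337e41f4669087ecbb44869dc  seed=2 
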