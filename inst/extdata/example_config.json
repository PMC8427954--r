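{
  "comment": "Example configuration. The pk block is a SYNTHETIC pediatric-scale parameter set for self-contained simulation; substitute real pump-model constants for any actual concentration comparison.",
  "model": { "ce50": [1.84, 2.64, 3.98, 4.78], "gamma": 5.76 },
  "pk": { "v1": 9.5, "k10": 0.08, "k12": 0.11, "k21": 0.055,
          "k13": 0.042, "k31": 0.0035, "ke0": 0.8 },
  "protocol": { "targets": [1, 2, 3, 4, 5, 6],
                "hold_after_reach": 120, "eval_step": 20 },
  "fit": { "n_starts": 5 },
  "seed": 20210909
}
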