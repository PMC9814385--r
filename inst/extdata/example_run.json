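{
  "out_dir": "artifacts",
  "seed": 11,
  "split_seed": 202,
  "model": {
    "embedding_dim": 64,
    "latent_dim": 32,
    "hidden_dim": 96,
    "recurrent_dropout": 0,
    "kl_weight": 0.1,
    "learning_rate": 0.002,
    "epochs": 200,
    "batch_size": 5,
    "lr_decay_at": [100, 150, 180],
    "lr_decay_factor": 0.4,
    "kl_anneal_epochs": 30,
    "seed": 303
  },
  "generator": {
    "n_equations": 500,
    "seed": 101
  },
  "generate_count": 5,
  "generate_count_mode": "survivors",
  "generate_mode": "perturb",
  "generate_perturb_sd": 0.4
}
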