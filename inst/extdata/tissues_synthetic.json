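{
  "comment": "SYNTHETIC tissue dielectric starter pack. Cole-Cole parameters chosen at literature scale for gel-moistened skin, subcutaneous (non-infiltrated) fat and skeletal muscle; NOT a transcription of any measured database. Constructed so that |eps*_muscle| > |eps*_fat| > |eps*_skin| over 0.1 Hz - 10 kHz. Validity capped at 41 kHz: the ordering is constructed to hold up to that bound (it crosses over near 56 kHz), covering the 4096-harmonic analysis of a 10 Hz pulse train.",
  "materials": [
    {
      "name": "skin",
      "eps_inf": 4.0,
      "sigma_static": 0.00043,
      "terms": [
        {
          "delta_eps": 39,
          "tau_s": 7.96e-12,
          "alpha": 0.1
        },
        {
          "delta_eps": 280,
          "tau_s": 7.96e-08,
          "alpha": 0.0
        },
        {
          "delta_eps": 10000.0,
          "tau_s": 1.59e-06,
          "alpha": 0.16
        },
        {
          "delta_eps": 40000.0,
          "tau_s": 0.00159,
          "alpha": 0.2
        }
      ],
      "f_max_hz": 41000.0
    },
    {
      "name": "fat",
      "eps_inf": 2.5,
      "sigma_static": 0.01,
      "terms": [
        {
          "delta_eps": 3,
          "tau_s": 7.96e-12,
          "alpha": 0.2
        },
        {
          "delta_eps": 15,
          "tau_s": 1.592e-08,
          "alpha": 0.1
        },
        {
          "delta_eps": 33000.0,
          "tau_s": 0.0001592,
          "alpha": 0.05
        },
        {
          "delta_eps": 10000000.0,
          "tau_s": 0.007958,
          "alpha": 0.01
        }
      ],
      "f_max_hz": 41000.0
    },
    {
      "name": "muscle",
      "eps_inf": 4.0,
      "sigma_static": 0.2,
      "terms": [
        {
          "delta_eps": 50,
          "tau_s": 7.23e-12,
          "alpha": 0.1
        },
        {
          "delta_eps": 7000,
          "tau_s": 3.537e-07,
          "alpha": 0.1
        },
        {
          "delta_eps": 1200000.0,
          "tau_s": 0.0003183,
          "alpha": 0.1
        },
        {
          "delta_eps": 25000000.0,
          "tau_s": 0.002274,
          "alpha": 0.1
        }
      ],
      "f_max_hz": 41000.0
    }
  ]
}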