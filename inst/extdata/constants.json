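{
  "version": "iupac-2021-subset-1.0",
  "electron_mass": 0.000548579909,
  "elements": {
    "H":  {"isotopes": [[1.00782503207, 0.999885], [2.01410177785, 0.000115]]},
    "C":  {"isotopes": [[12.0, 0.9893], [13.00335483507, 0.0107]]},
    "N":  {"isotopes": [[14.0030740048, 0.99636], [15.0001088989, 0.00364]]},
    "O":  {"isotopes": [[15.99491461956, 0.99757], [16.99913170, 0.00038], [17.99916040, 0.00205]]},
    "Na": {"isotopes": [[22.9897692809, 1.0]]},
    "P":  {"isotopes": [[30.97376163, 1.0]]},
    "S":  {"isotopes": [[31.97207100, 0.9499], [32.97145876, 0.0075], [33.96786690, 0.0425], [35.96708076, 0.0001]]}
  },
  "covalent_radii": {
    "H": 0.31, "C": 0.76, "N": 0.71, "O": 0.66, "Na": 1.66, "P": 1.07, "S": 1.05
  }
}
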