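{
  "Brancher": {
    "pairwise_fisher": {
      "error": "need at least two groups"
    },
    "letters": [],
    "logistic_bleaching": [
      {
        "year": 2015,
        "n": 7,
        "coefficients": {
          "(Intercept)": 27.4267027416429,
          "size": 2.68517649769733e-14
        },
        "se": {
          "(Intercept)": 1296946.0268442,
          "size": 280803.914609496
        },
        "p": {
          "(Intercept)": null,
          "size": null
        },
        "converged": false,
        "separation": true
      },
      {
        "year": 2019,
        "n": 7,
        "coefficients": {
          "(Intercept)": 2.15178774534971,
          "size": -0.259009560230746
        },
        "se": {
          "(Intercept)": 4.28374051036146,
          "size": 0.867414651285745
        },
        "p": {
          "(Intercept)": 0.615445855897998,
          "size": 0.765245665409564
        },
        "converged": true,
        "separation": false
      }
    ],
    "logistic_survivorship": {
      "n": 30,
      "coefficients": {
        "(Intercept)": -0.574976036924679,
        "x": -0.197135837170857,
        "siteSouth": -26.8517290730274,
        "x:siteSouth": 0.197135837424376
      },
      "se": {
        "(Intercept)": 1.94105449073681,
        "x": 0.456420220806802,
        "siteSouth": 1272844.06356317,
        "x:siteSouth": 254146.524502061
      },
      "p": {
        "(Intercept)": null,
        "x": null,
        "siteSouth": null,
        "x:siteSouth": null
      },
      "converged": false,
      "separation": true,
      "pairwise_contrasts": [
        {
          "group1": "North",
          "group2": "South",
          "estimate": -26.8517290730274,
          "se": 1272844.06356317,
          "p_raw": 0.999983167945965,
          "p_adj": 0.999983167945965,
          "significant": false,
          "_row": "siteSouth"
        }
      ]
    },
    "ancova": {
      "error": "no factor level reaches the minimum group size"
    },
    "diagnostics": []
  },
  "Encruster": {
    "pairwise_fisher": {
      "table": [
        {
          "thermally_tolerant": 3,
          "decreased": 5,
          "increased": 3,
          "high_susceptibility": 2,
          "_row": "North"
        },
        {
          "thermally_tolerant": 4,
          "decreased": 9,
          "increased": 1,
          "high_susceptibility": 1,
          "_row": "South"
        }
      ],
      "pairs": [
        {
          "group1": "North",
          "group2": "South",
          "p_raw": 0.541395207968772,
          "p_adj": 0.541395207968772,
          "significant": false,
          "monte_carlo": false
        }
      ],
      "letters": {
        "North": "a",
        "South": "a"
      }
    },
    "letters": {
      "North": "a",
      "South": "a"
    },
    "logistic_bleaching": [
      {
        "year": 2015,
        "n": 28,
        "coefficients": {
          "(Intercept)": 2.46834148731497,
          "size": -0.432023675706128
        },
        "se": {
          "(Intercept)": 1.56200398805429,
          "size": 0.317915124339229
        },
        "p": {
          "(Intercept)": 0.114051869857531,
          "size": 0.174169493290702
        },
        "converged": true,
        "separation": false
      },
      {
        "year": 2019,
        "n": 28,
        "coefficients": {
          "(Intercept)": -1.64516652340889,
          "size": 0.147953274835121
        },
        "se": {
          "(Intercept)": 1.58646071896472,
          "size": 0.307446494188757
        },
        "p": {
          "(Intercept)": 0.299733871957102,
          "size": 0.630351195827704
        },
        "converged": true,
        "separation": false
      }
    ],
    "logistic_survivorship": {
      "n": 30,
      "coefficients": {
        "(Intercept)": 0.543181216808582,
        "x": 0.285432428410807,
        "siteSouth": 26.8835215311381,
        "x:siteSouth": -0.285432429935587
      },
      "se": {
        "(Intercept)": 3.43955776109849,
        "x": 0.741448306843617,
        "siteSouth": 794739.169635375,
        "x:siteSouth": 175323.502431086
      },
      "p": {
        "(Intercept)": null,
        "x": null,
        "siteSouth": null,
        "x:siteSouth": null
      },
      "converged": false,
      "separation": true,
      "pairwise_contrasts": [
        {
          "group1": "North",
          "group2": "South",
          "estimate": 26.8835215311381,
          "se": 794739.169635375,
          "p_raw": 0.999973010079803,
          "p_adj": 0.999973010079803,
          "significant": false,
          "_row": "siteSouth"
        }
      ]
    },
    "ancova": {
      "n": 14,
      "slope": 0.844601465292457,
      "terms": [
        {
          "term": "x",
          "df": 1,
          "F": 62.9385209613202,
          "p": 4.09554371478295e-06
        }
      ],
      "dropped_levels": ["thermally_tolerant", "increased", "high_susceptibility"],
      "diagnostics": {
        "shapiro_p": 0.5282692062245,
        "cochran_C": null,
        "cochran_p": null
      }
    },
    "diagnostics": {
      "shapiro_p": 0.5282692062245,
      "cochran_C": null,
      "cochran_p": null
    }
  }
}
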