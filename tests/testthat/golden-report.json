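{
  "parameters": {
    "species": ["Mlig", "Mhys", "Mspi", "Mpus"],
    "reference": "Mlig",
    "alpha": 0.05,
    "contrast": "AvH",
    "cutoff": 2,
    "min_overlap": 1,
    "t_max": 10,
    "n_iter": 1000,
    "seed": 11
  },
  "counts": {
    "n_orthogroups": 60,
    "n_transcripts": 230
  },
  "annotation": {
    "n_with_reference": 52,
    "n_annotated": 12,
    "n_orphan_transcripts": 0,
    "label_totals": {
      "testis_region": 9,
      "neoblast_FACS": 3
    }
  },
  "de": {
    "consistent_up_first": 3,
    "consistent_up_second": 1,
    "inconsistent": 1,
    "not_eligible": 55,
    "n_eligible": 5
  },
  "divergence": {
    "n_alignments": 58,
    "n_usable": 28,
    "n_excluded_saturated": 0,
    "median_divergence": 0.46631221478
  },
  "divergence_shift": [
    {
      "family": "positional",
      "label": "testis_region",
      "n": 3,
      "reference_median": 0.46030426241,
      "statistic": 6,
      "p": 0.25,
      "degenerate": false,
      "p_adj": 0.25
    },
    {
      "family": "positional",
      "label": "ovary_region",
      "n": 0,
      "reference_median": null,
      "statistic": null,
      "p": null,
      "degenerate": null,
      "p_adj": null
    },
    {
      "family": "positional",
      "label": "tail_region",
      "n": 0,
      "reference_median": null,
      "statistic": null,
      "p": null,
      "degenerate": null,
      "p_adj": null
    },
    {
      "family": "neoblast",
      "label": "neoblast_FACS",
      "n": 3,
      "reference_median": 0.47101514157,
      "statistic": 0,
      "p": 0.25,
      "degenerate": false,
      "p_adj": 0.25
    },
    {
      "family": "neoblast",
      "label": "neoblast_strict",
      "n": 0,
      "reference_median": null,
      "statistic": null,
      "p": null,
      "degenerate": null,
      "p_adj": null
    },
    {
      "family": "social",
      "label": "OvI",
      "n": 0,
      "reference_median": null,
      "statistic": null,
      "p": null,
      "degenerate": null,
      "p_adj": null
    },
    {
      "family": "social",
      "label": "BOTH",
      "n": 0,
      "reference_median": null,
      "statistic": null,
      "p": null,
      "degenerate": null,
      "p_adj": null
    }
  ],
  "composition": [
    {
      "predicate": "complete",
      "label": "neoblast_FACS",
      "n_annotated": 3,
      "observed": 3,
      "expected": 1.655,
      "ci_lo": 0,
      "ci_hi": 3,
      "p": 0.32167832168,
      "n_iter": 1000,
      "seed": 12,
      "p_adj": 0.32567432567
    },
    {
      "predicate": "complete",
      "label": "testis_region",
      "n_annotated": 9,
      "observed": 3,
      "expected": 4.865,
      "ci_lo": 2,
      "ci_hi": 8,
      "p": 0.32567432567,
      "n_iter": 1000,
      "seed": 13,
      "p_adj": 0.32567432567
    },
    {
      "predicate": "pair_only",
      "label": "neoblast_FACS",
      "n_annotated": 3,
      "observed": 0,
      "expected": 0,
      "ci_lo": 0,
      "ci_hi": 0,
      "p": 1,
      "n_iter": 1000,
      "seed": 12,
      "p_adj": 1
    },
    {
      "predicate": "pair_only",
      "label": "testis_region",
      "n_annotated": 9,
      "observed": 0,
      "expected": 0,
      "ci_lo": 0,
      "ci_hi": 0,
      "p": 1,
      "n_iter": 1000,
      "seed": 13,
      "p_adj": 1
    }
  ],
  "signalp_gof": {
    "table": [
      {
        "category": "testis_region",
        "size": 3,
        "observed": 1,
        "expected": 0.21428571429,
        "residual": 0.78571428571
      },
      {
        "category": "no_annotation",
        "size": 25,
        "observed": 1,
        "expected": 1.7857142857,
        "residual": -0.78571428571
      }
    ],
    "chi2": 3.2266666667,
    "df": 1,
    "p": 0.07244801353
  },
  "warnings": {
    "n": 0,
    "messages": []
  }
}
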