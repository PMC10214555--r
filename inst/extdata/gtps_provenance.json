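{
  "dataset": "gtps_arms.csv",
  "description": "Arm-level VAS pain summaries (0-10 cm, end of follow-up) for eight published trials of conservative management of greater trochanteric pain syndrome. Values are transcribed from the trial reports' summary tables; per-arm sample sizes are reconstructed from the published totals by an equal split, with the first-listed (treatment) arm taking the extra patient when the total is odd.",
  "notes": [
    "Brinks 2011 reports VAS both 'at rest' and 'with activity' for the same 120 patients; both rows are kept under distinct outcome_label values and are merged by fixed-effect inverse-variance pooling before any between-study synthesis.",
    "Some secondary summaries of these eight trials state 596 patients in total; the per-study totals recorded here sum to 503. This dataset follows the per-study totals.",
    "The treatment-code alias 'CIS-U' occasionally seen in secondary text is normalized to 'CSI-U'."
  ],
  "studies": [
    {"study_id": "Begkas2020",   "citation": "Begkas D et al., 2020 (Athens)",      "comparison": "PRP-U vs CSI-U", "total_randomized": 24,  "arm_split": [12, 12], "vas": "T 1.52 +/- 0.505; C 6.98 +/- 0.691", "follow_up": "24 weeks"},
    {"study_id": "Bashkina2011", "citation": "Bashkina AS et al., 2011 (Russia)",   "comparison": "PRP-U vs CSI-U", "total_randomized": 40,  "arm_split": [20, 20], "vas": "T 0.43 +/- 0.69; C 4.55 +/- 2.52",  "follow_up": "6 months"},
    {"study_id": "Ramon2020",    "citation": "Ramon S et al., 2020 (Spain)",        "comparison": "ESWT vs EX",     "total_randomized": 100, "arm_split": [50, 50], "vas": "T 2.0 +/- 2.1; C 4.7 +/- 2.1",      "follow_up": "2 months as printed; study text reports up to 12 months"},
    {"study_id": "Furia2014",    "citation": "Furia JP et al., 2014 (Germany)",     "comparison": "ESWT vs EX",     "total_randomized": 32,  "arm_split": [16, 16], "vas": "T 2.7 +/- 0.9; C 6.3 +/- 1.2",      "follow_up": "12 months"},
    {"study_id": "Shi2021",      "citation": "Shi LJ et al., 2021 (China)",         "comparison": "ESWT vs EX",     "total_randomized": 53,  "arm_split": [27, 26], "vas": "T 3.20 +/- 0.81; C 6.3 +/- 1.4",    "follow_up": "6 months"},
    {"study_id": "Heaver2021",   "citation": "Heaver C et al., 2021 (England)",     "comparison": "ESWT vs CSI-U",  "total_randomized": 104, "arm_split": [52, 52], "vas": "T 4.0 +/- 2.5; C 4.82 +/- 2.65",    "follow_up": "12 months"},
    {"study_id": "Mitchell2018", "citation": "Mitchell WG et al., 2018 (USA)",      "comparison": "CSI-U vs CSI-B", "total_randomized": 30,  "arm_split": [15, 15], "vas": "T 1.3 +/- 1.9; C 2.2 +/- 2.5",      "follow_up": "6 months"},
    {"study_id": "Brinks2011",   "citation": "Brinks A et al., 2011 (Netherlands)", "comparison": "CSI-U vs UC",    "total_randomized": 120, "arm_split": [60, 60], "vas": "rest: T 2.1 +/- 2.5, C 2.3 +/- 2.3; activity: T 2.8 +/- 2.8, C 3.2 +/- 2.9", "follow_up": "12 months"}
  ]
}
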