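{
 "comment": "Built-in cytosine base editor presets. PAM/spacer/window values quoted per-editor from the primary literature (see 'source'). Window positions are 1-based from the 5' end of the protospacer as written 5'->3' (PAM-distal end for 3'-PAM editors, PAM-proximal end for 5'-PAM Cas12a).",
 "presets": [
  {"name": "BE3", "pam_pattern": "NGG", "pam_side": "3prime", "spacer_len": 20, "window_start": 4, "window_end": 8,
   "source": "Komor et al. 2016, Nature 533:420-424 (APOBEC1-nCas9-UGI; activity window ~4-8)"},
  {"name": "xBE3", "pam_pattern": "NG", "pam_side": "3prime", "spacer_len": 20, "window_start": 4, "window_end": 8,
   "source": "Hu et al. 2018, Nature 556:57-63 (xCas9 3.7 BE3; NG PAM)"},
  {"name": "BE-PLUS", "pam_pattern": "NGG", "pam_side": "3prime", "spacer_len": 20, "window_start": 4, "window_end": 16,
   "source": "Jiang et al. 2018, Cell Research 28:855-861 (SunTag-recruited APOBEC1; broadened window 4-16)"},
  {"name": "SaBE3", "pam_pattern": "NNGRRT", "pam_side": "3prime", "spacer_len": 21, "window_start": 3, "window_end": 12,
   "source": "Kim et al. 2017, Nat Biotechnol 35:371-376 (SaCas9 BE3; window ~3-12 of 21-nt spacer)"},
  {"name": "Sa(KKH)-BE3", "pam_pattern": "NNNRRT", "pam_side": "3prime", "spacer_len": 21, "window_start": 3, "window_end": 12,
   "source": "Kim et al. 2017, Nat Biotechnol 35:371-376 (SaCas9-KKH relaxed PAM)"},
  {"name": "VQR-BE3", "pam_pattern": "NGA", "pam_side": "3prime", "spacer_len": 20, "window_start": 4, "window_end": 11,
   "source": "Kim et al. 2017, Nat Biotechnol 35:371-376 (SpCas9-VQR; NGA PAM)"},
  {"name": "VRER-BE3", "pam_pattern": "NGCG", "pam_side": "3prime", "spacer_len": 20, "window_start": 4, "window_end": 11,
   "source": "Kim et al. 2017, Nat Biotechnol 35:371-376 (SpCas9-VRER; NGCG PAM)"},
  {"name": "YE1-BE3", "pam_pattern": "NGG", "pam_side": "3prime", "spacer_len": 20, "window_start": 4, "window_end": 7,
   "source": "Kim et al. 2017, Nat Biotechnol 35:371-376 (APOBEC1-YE1 narrowed window)"},
  {"name": "EE-BE3", "pam_pattern": "NGG", "pam_side": "3prime", "spacer_len": 20, "window_start": 5, "window_end": 6,
   "source": "Kim et al. 2017, Nat Biotechnol 35:371-376 (APOBEC1-EE narrowed window)"},
  {"name": "YEE-BE3", "pam_pattern": "NGG", "pam_side": "3prime", "spacer_len": 20, "window_start": 6, "window_end": 6,
   "source": "Kim et al. 2017, Nat Biotechnol 35:371-376 (APOBEC1-YEE; essentially position 6 only)"},
  {"name": "Target-AID", "pam_pattern": "NGG", "pam_side": "3prime", "spacer_len": 20, "window_start": 2, "window_end": 4,
   "source": "Nishida et al. 2016, Science 353:aaf8729 (PmCDA1 fusion; window ~2-4)"},
  {"name": "Target-AID-NG", "pam_pattern": "NG", "pam_side": "3prime", "spacer_len": 20, "window_start": 2, "window_end": 4,
   "source": "Nishimasu et al. 2018, Science 361:1259-1262 (SpCas9-NG Target-AID)"},
  {"name": "Cas12a-BE", "pam_pattern": "TTTV", "pam_side": "5prime", "spacer_len": 23, "window_start": 8, "window_end": 13,
   "source": "Li et al. 2018, Nat Biotechnol 36:324-327 (dCas12a/dCpf1-BE; T-rich 5' PAM, window ~8-13)"}
 ]
}
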