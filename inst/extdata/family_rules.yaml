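# Default processing grammars for the 21 single-copy neuropeptide precursor
# families of Polyneoptera. Motifs are prohormone-convertase basic cleavage
# sites (K/R only, length 1-4). n_flank may be the sentinel "signal_peptide",
# c_flank motif sets may be empty when allow_precursor_end is set.
# Length ranges are advisory (observed mature-peptide lengths in residues).
# Cores marked core_synthetic are stand-ins assembled around the family's
# conserved consensus/C-terminus where no complete ancestral peptide is known.
- family_id: ACP
  location: post_signal
  n_flank: [signal_peptide]
  c_flank: [KR]
  allow_precursor_end: no
  amidated: yes
  pglu_expected: yes
  retain_post_signal_basics: no
  length_min: 10
  length_max: 12
  ancestral_core: QVTFSRDWNA
  core_synthetic: no
  ancestral_depth: Hexapoda
- family_id: AST-CC
  location: c_terminal
  n_flank: [RR]
  c_flank: [KR, RR]
  allow_precursor_end: yes
  amidated: no
  pglu_expected: no
  retain_post_signal_basics: no
  length_min: 18
  length_max: 20
  ancestral_core: GQQKGRVYWRCYFNAVTCF
  core_synthetic: no
  ancestral_depth: Pterygota
- family_id: AST-CCC
  location: c_terminal
  n_flank: [KR]
  c_flank: [K, KK]
  allow_precursor_end: no
  amidated: yes
  pglu_expected: no
  retain_post_signal_basics: no
  length_min: 14
  length_max: 14
  ancestral_core: SYWKQCAFNAVSCF
  core_synthetic: no
  ancestral_depth: Hexapoda
- family_id: AT
  location: post_propeptide
  n_flank: [R]
  c_flank: [KR]
  allow_precursor_end: no
  amidated: yes
  pglu_expected: no
  retain_post_signal_basics: no
  length_min: 12
  length_max: 13
  ancestral_core: GFKNVALSTARGF
  core_synthetic: no
  ancestral_depth: Pterygota
  propeptide_len: 19
- family_id: CCAP
  location: post_propeptide
  n_flank: [KR]
  c_flank: [KKR, RKR]
  allow_precursor_end: no
  amidated: yes
  pglu_expected: no
  retain_post_signal_basics: no
  length_min: 9
  length_max: 9
  ancestral_core: PFCNAFTGC
  core_synthetic: no
  ancestral_depth: Hexapoda
  propeptide_len: 25
- family_id: CCHamide-1
  location: post_signal
  n_flank: [signal_peptide]
  c_flank: [KR]
  allow_precursor_end: no
  amidated: yes
  pglu_expected: no
  retain_post_signal_basics: no
  length_min: 14
  length_max: 14
  ancestral_core: GSCLSYGHSCWGAH
  core_synthetic: no
  ancestral_depth: Pterygota
- family_id: CCHamide-2
  location: post_signal
  n_flank: [signal_peptide]
  c_flank: [KR]
  allow_precursor_end: no
  amidated: yes
  pglu_expected: no
  retain_post_signal_basics: yes
  length_min: 14
  length_max: 16
  ancestral_core: KRGCSAFGHSCFGGH
  core_synthetic: no
  ancestral_depth: Pterygota
- family_id: CNMamide
  location: c_terminal
  n_flank: [KR, KK]
  c_flank: [RKR]
  allow_precursor_end: no
  amidated: yes
  pglu_expected: no
  retain_post_signal_basics: no
  length_min: 13
  length_max: 18
  ancestral_core: GSYMSLCHFKICNM
  core_synthetic: no
  ancestral_depth: Pterygota
- family_id: corazonin
  location: post_signal
  n_flank: [signal_peptide]
  c_flank: [RKR]
  allow_precursor_end: no
  amidated: yes
  pglu_expected: yes
  retain_post_signal_basics: no
  length_min: 9
  length_max: 11
  ancestral_core: QTFQYSRGWTN
  core_synthetic: no
  ancestral_depth: Hexapoda
- family_id: CRF-DH
  location: internal
  n_flank: [KR]
  c_flank: [KR, RKR]
  allow_precursor_end: no
  amidated: yes
  pglu_expected: no
  retain_post_signal_basics: no
  length_min: 42
  length_max: 46
  ancestral_core: AGALPSLSIVNPMDVLRQRLLLEIARRRMREEAQGAEANRQILLSL
  core_synthetic: yes
  ancestral_depth: undetermined
- family_id: CT-DH
  location: internal
  n_flank: [KR]
  c_flank: [RRRR, RKRR]
  allow_precursor_end: no
  amidated: yes
  pglu_expected: no
  retain_post_signal_basics: no
  length_min: 31
  length_max: 31
  ancestral_core: GLDLGLSRGFSGSQAAKHLMGLAAANYAGGP
  core_synthetic: no
  ancestral_depth: Pterygota
- family_id: elevenin
  location: post_signal
  n_flank: [signal_peptide]
  c_flank: [KR, RKR, KKR]
  allow_precursor_end: no
  amidated: no
  pglu_expected: no
  retain_post_signal_basics: no
  length_min: 17
  length_max: 22
  ancestral_core: ADLSSCNGNQLSCRGVAA
  core_synthetic: yes
  ancestral_depth: undetermined
- family_id: HanSolin
  location: c_terminal
  n_flank: [R, RR]
  c_flank: [RR, KR, R]
  allow_precursor_end: no
  amidated: yes
  pglu_expected: no
  retain_post_signal_basics: no
  length_min: 8
  length_max: 16
  ancestral_core: ADFSGQPLRW
  core_synthetic: yes
  ancestral_depth: undetermined
- family_id: MS
  location: c_terminal
  n_flank: [KR]
  c_flank: [RRR]
  allow_precursor_end: no
  amidated: yes
  pglu_expected: yes
  retain_post_signal_basics: no
  length_min: 10
  length_max: 11
  ancestral_core: QDVDHVFLRF
  core_synthetic: no
  ancestral_depth: Hexapoda
- family_id: NPF-1
  location: post_signal
  n_flank: [signal_peptide]
  c_flank: [KR]
  allow_precursor_end: no
  amidated: yes
  pglu_expected: no
  retain_post_signal_basics: no
  length_min: 30
  length_max: 36
  ancestral_core: ASFDDPSQLLAYNDQPALQELDRYYSQVARPRF
  core_synthetic: yes
  ancestral_depth: undetermined
- family_id: NPF-2
  location: post_signal
  n_flank: [signal_peptide]
  c_flank: [KR]
  allow_precursor_end: no
  amidated: yes
  pglu_expected: no
  retain_post_signal_basics: no
  length_min: 43
  length_max: 47
  ancestral_core: SNEALSAYDDALQYNAPEGSMANLAADFGSSPQAMQTSLARPRF
  core_synthetic: yes
  ancestral_depth: undetermined
- family_id: proctolin
  location: post_signal
  n_flank: [signal_peptide]
  c_flank: [R]
  allow_precursor_end: no
  amidated: no
  pglu_expected: no
  retain_post_signal_basics: no
  length_min: 5
  length_max: 5
  ancestral_core: RYLPT
  core_synthetic: no
  ancestral_depth: Hexapoda
- family_id: RFLamide
  location: c_terminal
  n_flank: [RKR, RRR, RR]
  c_flank: [R, RR, KR, RKR, RRR]
  allow_precursor_end: yes
  amidated: yes
  pglu_expected: no
  retain_post_signal_basics: no
  length_min: 12
  length_max: 14
  ancestral_core: PASAIFTNIRFL
  core_synthetic: no
  ancestral_depth: Polyneoptera
- family_id: SIFamide
  location: post_signal
  n_flank: [signal_peptide]
  c_flank: [KR]
  allow_precursor_end: no
  amidated: yes
  pglu_expected: no
  retain_post_signal_basics: no
  length_min: 11
  length_max: 12
  ancestral_core: TYRKPPFNGSIF
  core_synthetic: no
  ancestral_depth: Polyneoptera
- family_id: sNPF
  location: internal
  n_flank: [RK]
  c_flank: [RR]
  allow_precursor_end: no
  amidated: yes
  pglu_expected: no
  retain_post_signal_basics: no
  length_min: 11
  length_max: 11
  ancestral_core: SNRSPSLRLRF
  core_synthetic: no
  ancestral_depth: Pterygota
  secondary_site: 3
- family_id: trissin
  location: post_signal
  n_flank: [signal_peptide]
  c_flank: [RKR, KKR, KR]
  allow_precursor_end: no
  amidated: no
  pglu_expected: no
  retain_post_signal_basics: no
  length_min: 27
  length_max: 27
  ancestral_core: LSCDSCGRECXXXCGTRNFRTCCFNYL
  core_synthetic: no
  ancestral_depth: Pterygota
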