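# rf3_cut pattern library (6 expressions)
(?<![A-Za-z0-9])(?P<wt_res>[ACDEFGHIKLMNPQRSTVWY])(?P<pos>[1-9][0-9]*)(?P<mut_res>[ACDEFGHIKLMNPQRSTVWY])?(?![A-Za-z0-9])	[CASE_SENSITIVE]	[CUT]
(?<![A-Za-z0-9])(?P<wt_res>[ACDEFGHIKLMNPQRSTVWY]) (?P<pos>[1-9][0-9]*)(?P<mut_res>[ACDEFGHIKLMNPQRSTVWY])?(?![A-Za-z0-9])	[CASE_SENSITIVE]	[CUT]
(?<![A-Za-z0-9])(?P<wt_res>(?:Ala|Arg|Asn|Asp|Cys|Gln|Glu|Gly|His|Ile|Leu|Lys|Met|Phe|Pro|Ser|Thr|Trp|Tyr|Val))(?P<pos>[1-9][0-9]*)(?P<mut_res>(?:Ala|Arg|Asn|Asp|Cys|Gln|Glu|Gly|His|Ile|Leu|Lys|Met|Phe|Pro|Ser|Thr|Trp|Tyr|Val))?(?![A-Za-z0-9])	[CASE_SENSITIVE]	[CUT]
(?<![A-Za-z0-9])(?P<wt_res>(?:Ala|Arg|Asn|Asp|Cys|Gln|Glu|Gly|His|Ile|Leu|Lys|Met|Phe|Pro|Ser|Thr|Trp|Tyr|Val)) (?P<pos>[1-9][0-9]*)(?P<mut_res>(?:Ala|Arg|Asn|Asp|Cys|Gln|Glu|Gly|His|Ile|Leu|Lys|Met|Phe|Pro|Ser|Thr|Trp|Tyr|Val))?(?![A-Za-z0-9])	[CASE_SENSITIVE]	[CUT]
(?<![A-Za-z0-9])(?P<wt_res>(?i:alanine|arginine|asparagine|aspartic acid|cysteine|glutamine|glutamic acid|glycine|histidine|isoleucine|leucine|lysine|methionine|phenylalanine|proline|serine|threonine|tryptophan|tyrosine|valine|aspartate|glutamate))(?P<pos>[1-9][0-9]*)(?P<mut_res>(?i:alanine|arginine|asparagine|aspartic acid|cysteine|glutamine|glutamic acid|glycine|histidine|isoleucine|leucine|lysine|methionine|phenylalanine|proline|serine|threonine|tryptophan|tyrosine|valine|aspartate|glutamate))?(?![A-Za-z0-9])	[CASE_SENSITIVE]	[CUT]
(?<![A-Za-z0-9])(?P<wt_res>(?i:alanine|arginine|asparagine|aspartic acid|cysteine|glutamine|glutamic acid|glycine|histidine|isoleucine|leucine|lysine|methionine|phenylalanine|proline|serine|threonine|tryptophan|tyrosine|valine|aspartate|glutamate)) (?P<pos>[1-9][0-9]*)(?P<mut_res>(?i:alanine|arginine|asparagine|aspartic acid|cysteine|glutamine|glutamic acid|glycine|histidine|isoleucine|leucine|lysine|methionine|phenylalanine|proline|serine|threonine|tryptophan|tyrosine|valine|aspartate|glutamate))?(?![A-Za-z0-9])	[CASE_SENSITIVE]	[CUT]
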