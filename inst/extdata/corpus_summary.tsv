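quantity	count	denominator
articles_total	410364	NA
articles_with_mineable_supp	68995	410364
files_mineable	213245	NA
files_supp_cited	10179	213245
articles_body_cited	28610	410364
articles_both_body_and_supp	3365	410364
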