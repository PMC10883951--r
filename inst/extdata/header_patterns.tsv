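# Section-header and ingredient-label patterns, one per line:
# <pattern_id> TAB <kind:BEGIN|END|S1END|LABEL> TAB <regex>
# BEGIN marks the start of the composition section, END the header of the
# section that follows it.  S1END patterns delimit the end of Section 1 for
# the single-ingredient fallback.  LABEL patterns are ingredient-column
# label vocabulary.  All patterns are matched case-insensitively on raw
# (pre-stopword-removal) page text.
begin_sec3_comp	BEGIN	section\s*0*3\s*[:.\-]?\s*composition(\s*/?\s*(and\s+)?information\s+on\s+ingredients)?
begin_sec2_comp	BEGIN	section\s*0*2\s*[:.\-]?\s*composition(\s*/?\s*(and\s+)?information\s+on\s+ingredients)?
begin_comp_info	BEGIN	composition\s*[/,]?\s*(and\s+)?information\s+on\s+ingredients
begin_haz_ingr	BEGIN	hazardous\s+ingredients
end_sec4_first_aid	END	section\s*0*4\s*[:.\-]?\s*first[\s\-]*aid(\s+measures)?
end_first_aid	END	first[\s\-]*aid\s+measures
end_sec3_hazards	END	section\s*0*3\s*[:.\-]?\s*hazards?\s+identification
s1end_sec2	S1END	section\s*0*2\s*[:.\-]
label_cas	LABEL	\bcas\s*(registry\s*)?(no\b|no\.|number|#)
label_cas_col	LABEL	\bcas\s*:
label_name	LABEL	\b(chemical|ingredient|substance|component)\s+name
label_conc	LABEL	\bconcentration\b
label_wt	LABEL	\bw\s*t\s*\.?\s*%|\bwt\b|%\s*w/w|weight\s*(%|percent)
label_einecs	LABEL	\beinecs\b|\bec\s+number\b
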