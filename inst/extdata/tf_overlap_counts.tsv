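cell_type	factor_set	neither	expr_only	tfbs_only	both	universe
cd4_t_cells	max_correlated	1737	19	237	7	2000
neutrophils	max_correlated	1749	12	234	5	2000
monocytes	max_correlated	1739	17	237	7	2000
cd4_t_cells	clinically_correlated	1729	27	235	9	2000
neutrophils	clinically_correlated	1744	19	230	7	2000
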