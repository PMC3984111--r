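pool_set	raw_yield_gb	pct_mapped	pct_on_target	total_coverage	avg_coverage_per_pool	avg_coverage_per_sample
Matrix 1 Columns	25.41	64.66	78.98	51840	4320	360
Matrix 1 Rows	26.53	66.29	75.97	53424	4452	371
Matrix 2 Columns	41.37	75.10	74.62	92736	7728	644
Matrix 2 Rows	28.74	73.36	71.17	60048	5004	417
Matrix 3 Columns	70.86	79.64	72.13	162720	13560	1130
Matrix 3 Rows	29.87	76.59	78.81	72144	6012	501
Matrix 4 Columns	25.36	68.12	68.12	52416	4368	364
Matrix 4 Rows	24.33	73.20	73.20	54144	4512	376
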