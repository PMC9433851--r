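mode	subregion
1	L_CA23_head
1	L_CA23_body
1	R_CA23_head
1	L_CA4_head
1	R_CA4_head
1	L_CA4_body
1	L_DG_head
1	L_DG_body
1	R_DG_head
1	R_DG_body
1	L_HATA_head
1	R_HATA_head
1	L_PrS_head
1	L_Sub_body
1	R_Sub_body
2	L_Tail_body
2	R_Tail_body
2	L_Para_head
2	R_Para_head
2	L_PrS_head
2	R_PrS_head
2	L_Sub_body
3	L_CA23_head
3	R_CA23_head
3	R_Sub_head
4	L_PrS_head
4	L_Fimbria_body
4	L_HATA_head
5	R_Fimbria_body
5	R_PrS_head
5	R_Sub_head
5	R_ML_head
7	L_Para_head
1	L_Temporal_1
1	L_Temporal_2
1	L_Temporal_3
1	L_Temporal_4
1	L_Temporal_5
1	R_Temporal_1
1	R_Temporal_2
1	R_Temporal_3
1	L_Prefrontal_1
1	L_Prefrontal_2
1	L_Prefrontal_3
1	L_Prefrontal_4
1	R_Prefrontal_1
1	R_Prefrontal_2
1	R_Prefrontal_3
1	L_Parietal_1
1	L_Parietal_2
1	L_Parietal_3
1	L_Parietal_4
1	L_Parietal_5
1	R_Parietal_1
1	R_Parietal_2
1	R_Parietal_3
1	R_Parietal_4
1	R_Parietal_5
1	L_Posteriorcingulate_1
3	L_Prefrontal_5
3	L_Prefrontal_6
3	L_Prefrontal_7
3	L_Prefrontal_8
3	L_Prefrontal_9
3	L_Parietal_6
3	L_Parietal_7
4	R_Temporal_4
4	R_Prefrontal_4
4	R_Prefrontal_5
4	R_Posteriorcingulate_1
5	R_Posteriorcingulate_2
6	L_Temporal_5
6	L_Temporal_6
6	L_Temporal_7
6	L_Temporal_8
6	L_Temporal_9
6	L_Temporal_10
6	L_Temporal_11
6	L_Temporal_12
6	L_Parietal_8
6	L_Parietal_9
6	L_Posteriorcingulate_2
6	L_Posteriorcingulate_3
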