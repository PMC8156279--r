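family	group
miR1139	rare
miR2873	rare
miR5063	rare
miR5161	rare
miR5167	rare
miR5169	rare
miR5179	rare
miR531	rare
miR5566	rare
miR6224	rare
miR7708	rare
miR7709	rare
miR7717	rare
miR7726	rare
miR7729	rare
miR7745	rare
miR7748	rare
miR7763	rare
miR7765	rare
miR9494	rare
miR398	moderately_conserved
miR5068	moderately_conserved
miR5184	moderately_conserved
miR7725	moderately_conserved
miR7727	moderately_conserved
miR7744	moderately_conserved
miR7766	moderately_conserved
miR9480	moderately_conserved
miR9490	moderately_conserved
miR8155	moderately_conserved
miR394	highly_conserved
miR1133	highly_conserved
miR1436	highly_conserved
miR5062	highly_conserved
miR5163	highly_conserved
miR5201	highly_conserved
miR7715	highly_conserved
miR7722	highly_conserved
miR7732	highly_conserved
miR7736	highly_conserved
miR7740	highly_conserved
miR7754	highly_conserved
miR7756	highly_conserved
miR7771	highly_conserved
miR7775	highly_conserved
miR7781	highly_conserved
miR5281	highly_conserved
miR845	highly_conserved
miR1122	common
miR1127	common
miR1128	common
miR1130	common
miR1135	common
miR1432	common
miR1435	common
miR1439	common
miR5049	common
miR5054	common
miR5067	common
miR5070	common
miR5164	common
miR5165	common
miR5171	common
miR5174	common
miR5175	common
miR5176	common
miR5180	common
miR5181	common
miR5182	common
miR5183	common
miR5185	common
miR5198	common
miR5199	common
miR5200	common
miR5202	common
miR528	common
miR5522	common
miR5568	common
miR6197	common
miR7716	common
miR7723	common
miR7728	common
miR7731	common
miR7733	common
miR7738	common
miR7755	common
miR7770	common
miR7772	common
miR7773	common
miR7777	common
miR9481	common
miR9485	common
miR9486	common
miR9489	common
miR9493	common
miR9495	common
miR9783	common
miR156	common
miR159	common
miR160	common
miR166	common
miR171	common
miR395	common
miR396	common
miR164	common
miR169	common
miR397	common
miR165	common
miR167	common
miR172	common
miR393	common
miR2118	common
miR2275	common
miR399	common
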