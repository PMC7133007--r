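group	subject_id	sex	age	n_genotypes	n_isolates
Children	CHI_01_WZW	Male	5	1	12
Children	CHI_02_ZYC	Male	5	2	12
Children	CHI_03_WSC	Male	6	1	12
Children	CHI_04_JZH	Female	5	1	12
Children	CHI_05_XZM	Male	6	1	12
Children	CHI_06_XHR	Female	6	1	12
Children	CHI_07_SYF	Male	4	2	12
Children	CHI_08_ZJH	Female	6	1	12
Children	CHI_09_HJB	Male	5	2	12
Children	CHI_10_CYF	Female	3	2	12
Children	CHI_11_SRH	Male	3	2	12
Children	CHI_12_LBW	Male	4	3	12
Children	CHI_13_WYB	Female	3	1	12
Children	CHI_14_WYH	Female	3	1	12
Children	CHI_15_GB	Male	4	2	12
Children	CHI_16_KK	Male	6	1	12
Children	CHI_17_ZWH	Female	4	1	12
Children	CHI_18_CEY	Female	4	2	12
Children	CHI_19_HYX	Male	3	1	12
Children	CHI_20_QMZ	Male	3	1	12
Children	CHI_21_LMQ	Male	4	1	12
Children	CHI_22_XWR	Female	6	1	12
Children	CHI_23_YPY	Male	5	2	12
Children	CHI_24_SBW	Male	4	2	12
Children	CHI_25_ZAK	Female	4	3	12
Children	CHI_26_LJY	Female	6	1	12
Children	CHI_27_ZZJ	Male	5	3	12
Children	CHI_28_XHS	Male	4	1	12
Children	CHI_29_LZT	Male	5	1	12
Children	CHI_30_HYH	Female	5	1	12
Children	CHI_31_YZY	Female	5	1	12
Children	CHI_32_JYH	Female	5	4	12
Children	CHI_33_TEZ	Male	3	1	12
Children	CHI_34_WYF	Female	5	1	12
Children	CHI_35_XZH	Male	6	3	12
Children	CHI_36_ZHL	Male	4	3	12
Children	CHI_37_QJY	Male	6	1	12
Children	CHI_38_XZX	Female	4	2	12
Children	CHI_39_DYL	Female	4	2	12
Children	CHI_40_YPY	Female	6	2	12
Children	CHI_41_LTW	Male	5	3	12
Children	CHI_42_CPY	Male	6	2	12
Children	CHI_43_WJS	Male	6	1	12
Children	CHI_44_HBY	Male	5	3	12
Children	CHI_45_GRY	Female	3	2	12
Children	CHI_46_LEQ	Female	3	2	12
Children	CHI_47_LZY	Male	4	1	12
Children	CHI_48_XWQ	Female	4	2	12
Children	CHI_49_WZH	Male	6	3	12
Children	CHI_50_JYX	Male	5	2	12
Children	CHI_51_YCX	Female	3	1	12
Children	CHI_52_ZJH	Female	3	1	12
Children	CHI_53_PJY	Male	6	1	12
Children	CHI_54_LXZ	Male	5	1	12
Children	CHI_55_SYZ	Male	3	1	12
Children	CHI_56_FSK	Female	3	1	12
Children	CHI_57_WC	Male	3	2	12
Children	CHI_58_RHM	Female	6	1	12
Children	CHI_59_CBC	Female	4	1	12
Children	CHI_60_ZMX	Female	5	2	12
Children	CHI_61_WX	Female	3	1	12
Children	CHI_62_WJT	Female	3	3	12
Children	CHI_63_LXY	Female	4	2	12
Children	CHI_64_YQT	Female	3	1	12
Children	CHI_65_LZR	Male	3	2	12
Children	CHI_66_TZL	Male	5	1	12
Children	CHI_67_YZY	Female	5	1	12
Children	CHI_68_ZYJ	Female	4	1	12
Students	STU_01_YZY	Female	18	2	12
Students	STU_02_WB	Male	17	5	12
Students	STU_03_YX	Male	17	2	12
Students	STU_04_DSJ	Female	21	1	12
Students	STU_05_AB	Male	19	5	12
Students	STU_06_TWX	Male	19	3	12
Students	STU_07_MP	Male	18	4	12
Students	STU_08_ZGQ	Female	20	6	12
Students	STU_09_YX	Male	20	7	12
Students	STU_10_WHY	Female	19	4	12
Students	STU_11_FCL	Female	20	3	12
Students	STU_12_HSJ	Female	19	2	12
Students	STU_13_ZJL	Female	20	4	12
Students	STU_14_GMQ	Female	22	6	12
Students	STU_15_ZSY	Female	21	1	12
Students	STU_16_TZL	Male	20	7	12
Students	STU_17_LL	Female	20	5	12
Students	STU_18_SMN	Female	20	3	12
Students	STU_19_LY	Female	19	3	12
Students	STU_20_YZR	Female	20	4	12
Students	STU_21_CPP	Female	21	4	12
Students	STU_22_CH	Male	21	1	12
Students	STU_23_WQY	Male	19	2	12
Students	STU_24_HQ	Female	19	1	12
Students	STU_25_FC	Male	22	3	12
Students	STU_26_ZS	Female	21	6	12
Students	STU_27_MWH	Female	19	4	12
Students	STU_28_SQ	Male	22	4	12
Students	STU_29_LSY	Female	18	3	12
Students	STU_30_YXX	Male	20	3	12
Students	STU_31_ZYX	Male	20	3	12
Students	STU_32_FYJ	Female	22	2	12
Students	STU_33_MHY	Female	21	7	12
Students	STU_34_XXM	Female	19	2	12
Students	STU_35_BJ	Female	18	2	12
Students	STU_36_CS	Male	21	4	12
Students	STU_37_SX	Female	21	1	12
Students	STU_38_CYB	Female	21	5	12
Students	STU_39_LHM	Female	21	2	12
Students	STU_40_LYY	Female	20	2	12
Students	STU_41_WRM	Female	19	2	12
Students	STU_42_WY	Male	19	2	12
Students	STU_43_LXL	Female	22	1	12
Students	STU_44_WYJ	Female	19	2	12
Students	STU_45_LHC	Male	20	7	12
Students	STU_46_SR	Female	20	3	12
Students	STU_47_HL	Female	21	2	12
Students	STU_48_CYJ	Female	22	1	12
Students	STU_49_WYT	Female	21	3	12
Students	STU_50_ZQZ	Female	22	1	12
Students	STU_51_ZJB	Male	21	4	12
Students	STU_52_ZWL	Male	20	1	12
Students	STU_53_WHR	Female	21	4	12
Students	STU_54_ZYZ	Male	19	6	12
Students	STU_55_WJJ	Female	19	4	12
Students	STU_56_QJ	Female	19	2	12
Students	STU_57_WYY	Female	18	2	12
Students	STU_58_LJ	Female	19	3	12
Students	STU_59_SN	Female	18	2	12
Students	STU_60_WSL	Female	21	5	12
Students	STU_61_SH	Male	20	4	12
Students	STU_62_LYY	Female	20	2	12
Students	STU_63_JHN	Male	20	4	12
Students	STU_64_YMX	Female	20	2	12
Students	STU_65_XKL	Female	19	3	12
Students	STU_66_XX	Female	20	3	12
Students	STU_67_WY	Male	20	2	12
Students	STU_68_YR	Female	19	3	12
Students	STU_69_MXL	Female	19	5	12
Students	STU_70_GS	Female	19	2	12
Students	STU_71_LZY	Female	19	2	12
Students	STU_72_TR	Female	19	2	12
Students	STU_73_SHY	Female	19	1	12
Students	STU_74_GYX	Female	21	3	12
Students	STU_75_WL	Female	19	2	12
Students	STU_76_LLJ	Female	19	1	12
Students	STU_77_SYH	Female	19	3	12
Students	STU_78_MZY	Female	19	1	12
Students	STU_79_BZ	Male	18	2	12
Students	STU_80_FXF	Female	20	3	12
Students	STU_81_HJ	Female	19	1	12
Students	STU_82_HKP	Male	20	1	12
Students	STU_83_FR	Female	18	2	12
Students	STU_84_JT	Female	18	1	12
Students	STU_85_WL	Female	19	4	12
Students	STU_86_PHM	Female	17	4	12
Students	STU_87_ZMM	Female	19	2	12
Seniors	SEN_01_BMS1	Female	106	5	16
Seniors	SEN_02_BMS2	Female	90	5	16
Seniors	SEN_03_BMS3	Male	91	5	16
Seniors	SEN_04_BMS4	Female	105	6	16
Seniors	SEN_05_BMS5	Female	102	4	16
Seniors	SEN_06_BMS6	Female	96	4	16
Seniors	SEN_07_BMS9	Male	93	4	16
Seniors	SEN_08_BMS11	Female	100	5	16
Seniors	SEN_09_BMS12	Female	101	5	16
Seniors	SEN_10_BMS17	Male	94	5	16
Seniors	SEN_11_BMS18	Female	103	13	16
Seniors	SEN_12_BMS21	Female	98	13	16
Seniors	SEN_13_BMS28	Male	92	5	16
Seniors	SEN_14_BMS63	Female	93	3	16
Seniors	SEN_15_BMS67	Female	96	8	16
CRC	CRC_01_LSJ	Female	68	2	12
CRC	CRC_02_ZFQ	Female	63	1	12
CRC	CRC_03_LJH	Female	45	2	12
CRC	CRC_04_SSR	Male	75	1	12
CRC	CRC_05_CYZ	Male	61	1	12
CRC	CRC_06_LDP	Male	52	1	12
CRC	CRC_07_GJB	Male	56	1	12
CRC	CRC_08_WWX	Male	57	1	12
CRC	CRC_09_ZMD	Female	61	1	12
CRC	CRC_10_BZZ	Female	77	4	12
CRC	CRC_11_ZSH	Female	61	1	12
CRC	CRC_12_ZWF	Male	61	1	12
CRC	CRC_13_ZYM	Male	38	4	12
CRC	CRC_14_BZS	Male	64	3	12
CRC	CRC_15_CYT	Male	34	3	12
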