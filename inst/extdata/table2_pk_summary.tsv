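trial	dose_regimen	day	population	cmax_obs	cmax_sim	auc_obs	auc_sim	ctrough_obs	ctrough_sim	tmax_obs	tmax_sim	pe_cmax_printed	pe_auc_printed
clarithromycin_ddi_control	40 mg single	1	HV	567	625	6040	5490	NA	NA	2.02	1.20	10.2	-9.11
rifampicin_ddi_control	40 mg single	1	HV	595	627	5870	5520	NA	NA	2.00	1.20	5.38	-5.96
itraconazole_ddi_control	40 mg single	1	HV	594	623	6000	5436	NA	NA	2.01	1.20	4.88	-9.40
fasted_control	40 mg single	1	HV	589	619	6040	5299	NA	NA	2.01	1.25	5.09	-12.3
hi_control	40 mg single	1	HV	584	659	5000	6306	NA	NA	2.00	1.22	12.8	26.1
ri_control	40 mg single	1	HV	584	696	5720	6904	NA	NA	2.03	1.26	19.2	20.7
fih_20bid_d1	20 mg BID	1	cancer	249	305	1053	1529	NA	NA	2.07	1.20	22.5	45.2
fih_20bid_d15	20 mg BID	15	cancer	339	445	2515	3216	114	149	2.98	1.14	31.3	27.9
fih_20bid_d28	20 mg BID	28	cancer	537	445	2977	3216	128	149	2.03	1.15	-17.1	8.03
fih_40bid_d1	40 mg BID	1	cancer	653	618	2695	3187	NA	NA	2.10	1.24	-5.36	18.3
fih_40bid_d15	40 mg BID	15	cancer	806	980	5519	7545	309	385	2.11	1.18	21.6	36.7
fih_40bid_d28	40 mg BID	28	cancer	873	980	5777	7544	308	384	2.01	1.15	12.3	30.6
fih_80bid_d1	80 mg BID	1	cancer	1365	1206	5628	6308	NA	NA	2.88	1.24	-11.6	12.1
fih_80bid_d15	80 mg BID	15	cancer	2127	1939	11971	15100	1087	780	2.13	1.18	-8.84	26.1
fih_80bid_d28	80 mg BID	28	cancer	2165	1939	14327	15096	1020	779	2.02	1.19	-10.4	5.37
fih_160bid_d1	160 mg BID	1	cancer	2923	2508	13706	13360	NA	NA	2.10	1.24	-14.2	-2.52
fih_160bid_d15	160 mg BID	15	cancer	4327	4373	30577	35506	2193	1962	2.17	1.18	1.06	16.1
fih_160bid_d28	160 mg BID	28	cancer	4809	4373	32768	35495	2559	1960	2.02	1.17	-9.07	8.32
fih_200bid_d1	200 mg BID	1	cancer	3646	3275	16788	17646	NA	NA	2.03	1.28	-10.2	5.11
fih_200bid_d15	200 mg BID	15	cancer	5700	6052	45641	50649	3191	2910	2.10	1.22	6.18	11.0
fih_200bid_d28	200 mg BID	28	cancer	6069	6050	40639	50622	3137	2906	2.00	1.19	-0.31	24.6
fih_80qd_d1	80 mg QD	1	cancer	1253	1301	5780	6874	NA	NA	2.06	1.22	3.83	18.9
fih_80qd_d15	80 mg QD	15	cancer	1595	1587	14702	17541	227	303	2.15	1.18	-0.50	19.3
fih_80qd_d28	80 mg QD	28	cancer	1826	1587	15633	17544	208	303	2.00	1.19	-13.1	12.2
fih_120qd_d1	120 mg QD	1	cancer	2199	1942	9543	10333	NA	NA	2.04	1.22	11.7	8.28
fih_120qd_d15	120 mg QD	15	cancer	2405	2396	21924	26948	342	481	2.03	1.22	-0.37	22.9
fih_120qd_d28	120 mg QD	28	cancer	2547	2396	21829	26956	332	480	2.00	1.22	-5.93	23.5
fih_200qd_d1	200 mg QD	1	cancer	3963	3271	17234	17482	NA	NA	2.00	1.22	-17.5	1.44
fih_200qd_d15	200 mg QD	15	cancer	4228	4152	40612	48302	787	928	2.05	1.18	-1.80	18.9
fih_200qd_d28	200 mg QD	28	cancer	4502	4152	39144	48309	523	927	2.02	1.19	-7.77	23.4
phase3_40bid_d15	40 mg BID	15	cancer	1010	1030	6070	8062	324	422	1.97	1.16	1.98	32.8
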