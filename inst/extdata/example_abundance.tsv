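metabolite	flfl_t0_r1	flfl_t0_r2	flfl_t0_r3	flfl_t0_r4	flfl_t20_r1	flfl_t20_r2	flfl_t20_r3	flfl_t20_r4	r26_t0_r1	r26_t0_r2	r26_t0_r3	r26_t0_r4	r26_t20_r1	r26_t20_r2	r26_t20_r3	r26_t20_r4
glucose	128.646387335141	96.0186743207129	126.973586817749	111.219402066602	92.2804627111845	90.0449306650833	107.313898865008	69.7920183149536	102.141207737283	106.833982449717	104.513329396933	103.578372454172	45.5898312216481	63.457542350139	39.8782506562305	55.0077714145762
glutamine	70.1462402784775	105.822315684452	123.379943183729	74.1523828838238	55.1271335116788	74.5497049479571	90.1976898490537	67.1588218706127	73.0330220860946	66.8015436004637	67.1670694488934	89.7424705234498	81.3775752520943	83.8415223949867	77.0577828959075	91.3362805199239
glycine	52.6848215784328	48.1184733443931	37.2391124732367	28.9717834526081	47.387844820255	34.578494816468	60.1840175594612	41.4255167064023	56.9720595509424	65.2617195720401	66.9853001221901	49.9091000259817	55.0167838772352	60.2245864545445	55.472952391558	53.7454064831186
serine	55.5757053546505	73.1232023907042	46.3954181697248	30.2379333757404	62.3628346319398	53.7063552287665	43.4590679987526	30.3955936915002	42.4571115255648	45.0137542701482	55.6862825054183	27.1032731946537	64.6908396883172	58.8361087326994	40.5921535214598	41.1404392785702
arginine	31.869492790992	29.054314350296	28.6508689992047	38.2072457482027	42.8161474542498	25.9154944613971	32.5113561669649	29.628621172016	22.4347172491417	33.496232660957	29.9450316019986	31.1248293509442	25.4713045119723	33.9317557162671	26.4190148982937	23.6599559302216
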