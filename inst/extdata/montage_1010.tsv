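name	x	y	z
Fp1	-0.286415715	0.955228655	-0.074190659
Fp2	0.271995142	0.959399105	-0.074645827
F7	-0.759250432	0.637455106	-0.131109760
F3	-0.531011305	0.730747935	0.428992365
Fz	-0.005919379	0.756129572	0.654395165
F4	0.527742691	0.741735654	0.413903215
F8	0.753058363	0.644091356	-0.134348153
FC5	-0.876176051	0.402878684	0.264583245
FC1	-0.361504640	0.447532983	0.817941700
FC2	0.354497906	0.457429495	0.815530191
FC6	0.872426306	0.412901801	0.261504193
T7	-0.992759186	0.014692100	-0.119219715
C3	-0.720702966	0.061406747	0.690518969
Cz	-0.005061083	0.081345285	0.996673131
C4	0.724277546	0.069759641	0.685970575
T8	0.992160114	0.026606977	-0.122108052
CP5	-0.886704032	-0.322450812	0.331332814
CP1	-0.356984483	-0.294207493	0.886568683
CP2	0.368195838	-0.292718101	0.882466962
CP6	0.891649024	-0.311838921	0.328204973
P7	-0.793355192	-0.607675182	-0.036309962
P3	-0.546758303	-0.623807092	0.558498049
Pz	-0.005599888	-0.615477356	0.788134674
P4	0.551601209	-0.617290282	0.560971313
P8	0.790529746	-0.611283165	-0.037357916
PO9	-0.533179570	-0.771525543	-0.347084835
O1	-0.302579528	-0.949799975	0.079533869
Oz	-0.008093614	-0.990139490	0.139850932
O2	0.290796976	-0.953459925	0.079694982
PO10	0.520853266	-0.778297806	-0.350662802
AF7	-0.541214618	0.833491702	-0.111257901
AF3	-0.338212160	0.919798315	0.198956265
AF4	0.336776089	0.919215042	0.204023461
AF8	0.530139125	0.840430443	-0.112379617
F5	-0.696985959	0.696363322	0.171139408
F1	-0.286159769	0.747695892	0.599219024
F2	0.287999456	0.753801386	0.590626603
F6	0.697336782	0.698363336	0.161276359
FT9	-0.815191123	0.305474987	-0.492085831
FT7	-0.924752142	0.355473938	-0.135910837
FC3	-0.669696230	0.438448898	0.599390961
FC4	0.667881055	0.446074045	0.595779190
FT8	0.918235627	0.371044967	-0.138452035
FT10	0.809426116	0.307809972	-0.500082377
C5	-0.943519648	0.040884449	0.328784331
C1	-0.383774404	0.075522889	0.920333363
C2	0.385968685	0.080345474	0.919006409
C6	0.944565976	0.051505475	0.324256540
TP7	-0.944511831	-0.316660554	-0.087312628
CP3	-0.670879958	-0.309424734	0.673926121
CPz	-0.005043875	-0.291540900	0.956545066
CP4	0.678910776	-0.303358120	0.668620976
TP8	0.944715954	-0.315499657	-0.089284560
P5	-0.723183708	-0.625970371	0.291832860
P1	-0.289078130	-0.619234418	0.730056553
P2	0.299685440	-0.610783859	0.732892703
P6	0.719585468	-0.629822820	0.292437976
PO7	-0.570399772	-0.821131644	0.019670384
PO3	-0.379865161	-0.848475376	0.368499655
POz	-0.007011428	-0.862813179	0.505474290
PO4	0.367433881	-0.855918288	0.363862925
PO8	0.563084274	-0.826178038	0.019129810
TP9	-0.843964402	-0.285179218	-0.454309258
TP10	0.838483458	-0.292662550	-0.459667404
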