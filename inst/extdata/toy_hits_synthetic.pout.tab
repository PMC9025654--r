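PSMId	peptide	score	q-value	posterior_error_prob	proteinIds
psm001	K.YLPLFRVNV.V	4.835	0.00239	0.00120	HOST00001
psm002	K.MLSGMIDDV.V	4.747	0.00335	0.00168	HOST00002
psm003	K.VLDESEFSV.V	5.697	0.00516	0.00258	HOST00003
psm004	K.QLPAAVQLV.V	5.557	0.00817	0.00409	HOST00004
psm005	K.DLGVERSLV.V	4.311	0.00182	0.00091	HOST00005
psm006	K.KLLLVNLKV.V	4.293	0.00809	0.00404	HOST00006
psm007	K.PLAWAAQKI.V	5.365	0.00850	0.00425	HOST00007
psm008	K.ALTNCHLGP.V	5.769	0.00595	0.00298	HOST00008
psm009	K.DEMLIAATV.V	4.888	0.00566	0.00283	HOST00009
psm010	K.TLKFLLDHV.V	5.881	0.00056	0.00028	HOST00010
psm011	K.ILRKGFEKV.V	5.398	0.00185	0.00093	HOST00011
psm012	K.TLGSMKGAV.V	4.388	0.00159	0.00080	HOST00012
psm013	K.MLKLVDSKV.V	5.341	0.00618	0.00309	HOST00013
psm014	K.VLGKDGFPV.V	3.871	0.00346	0.00173	HOST00014
psm015	K.ILSLYTEDV.V	6.433	0.00693	0.00347	HOST00015
psm016	K.MLVGWILGA.V	6.980	0.00448	0.00224	HOST00016
psm017	K.CLAKSHYEV.V	4.633	0.00646	0.00323	HOST00017
psm018	K.ANGISYMEV.V	3.956	0.00893	0.00447	HOST00018
psm019	K.IPTAAKIYV.V	5.570	0.00342	0.00171	HOST00019
psm020	K.KGSAVLIGV.V	4.865	0.00700	0.00350	HOST00020
psm021	K.YLSIKLRTL.V	7.402	0.00841	0.00421	HOST00021
psm022	K.ALIMMKYAV.V	4.961	0.00191	0.00096	HOST00022
psm023	K.CGSEEDAAV.V	5.690	0.00587	0.00294	HOST00023
psm024	K.MLAGQSNLV.V	5.028	0.00113	0.00056	HOST00024
psm025	K.LLQVTFGYV.V	4.257	0.00240	0.00120	HOST00025
psm026	K.KLRKPARVV.V	5.189	0.00348	0.00174	HOST00026
psm027	K.SLNLYCQFV.V	3.195	0.00012	0.00006	HOST00027
psm028	K.YLPNLVAPL.V	6.466	0.00344	0.00172	HOST00028
psm029	K.SQYAALFNV.V	5.153	0.00783	0.00392	HOST00029
psm030	K.QFFKSESGV.V	7.173	0.00306	0.00153	HOST00030
psm031	K.PGVRDAFLK.V	5.476	0.00434	0.00217	HOST00031
psm032	K.NGVRIRGLL.V	4.290	0.00540	0.00270	HOST00032
psm033	K.SLPTKGLVV.V	5.611	0.00444	0.00222	HOST00033
psm034	K.TLPAVTLEV.V	4.066	0.00168	0.00084	HOST00034
psm035	K.LLYVNACPV.V	3.746	0.00745	0.00373	HOST00035
psm036	K.QINMVAIVI.V	5.291	0.00602	0.00301	HOST00036
psm037	K.LVAISVQKV.V	4.557	0.00715	0.00358	HOST00037
psm038	K.GLVALPSPV.V	5.001	0.00097	0.00049	HOST00038
psm039	K.YLGFNSIDV.V	5.074	0.00651	0.00326	HOST00039
psm040	K.RLNGELGGV.V	4.410	0.00370	0.00185	HOST00040
psm041	K.ELAYLAPWF.V	4.431	0.00739	0.00369	HOST00041
psm042	K.SLAFLIVLP.V	4.865	0.00582	0.00291	HOST00042
psm043	K.LLLAHCAGV.V	6.178	0.00705	0.00352	HOST00043
psm044	K.HILNENLDQ.V	3.476	0.00498	0.00249	HOST00044
psm045	K.SLKINKALR.V	5.594	0.00477	0.00238	HOST00045
psm046	K.HLAAYLALV.V	5.333	0.00710	0.00355	HOST00046
psm047	K.FLPFSIKRV.V	6.063	0.00021	0.00011	HOST00047
psm048	K.DLTERENRV.V	4.696	0.00430	0.00215	HOST00048
psm049	K.HAFELTAGV.V	5.370	0.00659	0.00330	HOST00049
psm050	K.RLKSAKFYV.V	5.267	0.00623	0.00312	HOST00050
psm051	K.EPQIPKRDV.V	4.457	0.00430	0.00215	HOST00051
psm052	K.EFSEIKADV.V	6.208	0.00775	0.00387	HOST00052
psm053	K.SLAITSYGG.V	6.160	0.00394	0.00197	HOST00053
psm054	K.NASLMLVIT.V	5.700	0.00220	0.00110	HOST00054
psm055	K.LTHGIMACV.V	6.587	0.00064	0.00032	HOST00055
psm056	K.PLICILPWI.V	5.558	0.00090	0.00045	HOST00056
psm057	K.DLVEKSGSV.V	3.723	0.00285	0.00143	HOST00057
psm058	K.ANVADGVTG.V	4.427	0.00467	0.00233	HOST00058
psm059	K.VKKIVAKVV.V	3.775	0.00596	0.00298	HOST00059
psm060	K.KLDLCIEQV.V	4.527	0.00366	0.00183	HOST00060
psm061	K.DIEEDDASI.V	4.380	0.00822	0.00411	HOST00061
psm062	K.CLLLRYVWV.V	5.042	0.00264	0.00132	HOST00062
psm063	K.PVSFREENV.V	4.089	0.00413	0.00206	HOST00063
psm064	K.KLQTYQRIE.V	5.158	0.00299	0.00150	HOST00064
psm065	K.QLRVSVNKV.V	4.345	0.00586	0.00293	HOST00065
psm066	K.GLESVIMEV.V	6.767	0.00232	0.00116	HOST00066
psm067	K.VLKELAQLV.V	5.717	0.00431	0.00215	HOST00067
psm068	K.QEFLENAIV.V	5.910	0.00690	0.00345	HOST00068
psm069	K.TGIPPDDIV.V	5.384	0.00076	0.00038	HOST00069
psm070	K.GSARALTVV.V	6.682	0.00788	0.00394	HOST00070
psm071	K.LLKATSLPV.V	4.364	0.00305	0.00153	HOST00071
psm072	K.AQHLHSYVV.V	4.538	0.00755	0.00378	HOST00072
psm073	K.GLVIGTIKV.V	6.432	0.00312	0.00156	HOST00073
psm074	K.ILNSADVIR.V	4.349	0.00300	0.00150	HOST00074
psm075	K.GAVLLSQPA.V	4.793	0.00429	0.00215	HOST00075
psm076	K.TLGEQVGAF.V	4.607	0.00803	0.00402	HOST00076
psm077	K.ETFKPPEEE.V	4.680	0.00778	0.00389	HOST00077
psm078	K.QKQMITRPV.V	4.721	0.00351	0.00176	HOST00078
psm079	K.ARLYGGFNL.V	5.494	0.00700	0.00350	HOST00079
psm080	K.AATITVFTD.V	4.823	0.00865	0.00432	HOST00080
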