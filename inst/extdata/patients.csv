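"patient_id","true_d50","true_dx","age_at_sampling","gender","phenotype","ftd","umn_regions","lmn_regions","sampling_rd50","survival_months","event"
"ALS0001",26.6649775348659,9.46089260414619,75.7242932142941,"male","classic",FALSE,0,4,0.315782516060298,44.5711967366864,TRUE
"ALS0002",71.8562815632854,18.7818771467931,67.3568329935572,"female","classic",FALSE,3,3,0.0737612287510036,113.086268271479,TRUE
"ALS0003",28.1161675281201,8.45403432521269,62.4619495941709,"female","classic",FALSE,2,2,0.0942460690764692,50.9757635113471,TRUE
"ALS0004",31.4119719075215,9.94815152087915,61.8765378784977,"male","bulbar",FALSE,0,4,0.404122813722202,34.7064051186166,TRUE
"ALS0005",61.2486383556299,18.1842277832526,63.2800215878067,"male","classic",TRUE,1,4,0.114565044896101,84.3984805068094,TRUE
"ALS0006",28.016548909845,6.47653114433411,48.6241375917002,"male","pyramidal",FALSE,0,2,0.1496680570897,24.0038312981067,TRUE
"ALS0007",13.6657557615547,2.50510402835651,68.9625901661066,"male","classic",FALSE,1,0,0.389170238919227,21.0627864801093,TRUE
"ALS0008",19.6131533287604,6.06796096879242,79.8217608051942,"male","classic",FALSE,3,4,0.27443782569051,3.27971472139191,FALSE
"ALS0009",27.6088893174129,7.58020289705526,70.1266630705141,"male","classic",FALSE,4,3,0.239411664895909,31.9071945609175,TRUE
"ALS0010",28.4238491857571,5.08713863349198,74.7658331201856,"male","classic",FALSE,4,4,0.0719754399438698,57.3127963857919,TRUE
"ALS0011",27.1374097819482,6.29982910667911,68.8258599988644,"female","classic",FALSE,4,3,0.248175193600627,66.2041756911619,TRUE
"ALS0012",34.3372372351051,9.77312997767,67.5699880542341,"female","classic",FALSE,0,4,0.357859754503122,34.61245751761,FALSE
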