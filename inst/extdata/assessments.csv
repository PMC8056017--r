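"patient_id","t_months","alsfrs_r"
"ALS0001",10.8406673933025,45
"ALS0001",13.8406673933025,40
"ALS0001",16.8406673933025,34
"ALS0001",19.8406673933025,30
"ALS0001",22.8406673933025,28
"ALS0002",4.60041524317204,48
"ALS0002",7.60041524317204,46
"ALS0002",10.600415243172,46
"ALS0002",13.600415243172,43
"ALS0002",16.600415243172,45
"ALS0003",0.5,48
"ALS0003",3.5,45
"ALS0003",6.5,44
"ALS0003",9.5,45
"ALS0003",12.5,43
"ALS0004",19.3885889436607,40
"ALS0004",22.3885889436607,38
"ALS0004",25.3885889436607,30
"ALS0004",28.3885889436607,26
"ALS0004",31.3885889436607,25
"ALS0005",8.03390600607556,46
"ALS0005",11.0339060060756,46
"ALS0005",14.0339060060756,43
"ALS0005",17.0339060060756,44
"ALS0005",20.0339060060756,45
"ALS0006",2.38636488339013,46
"ALS0006",5.38636488339013,48
"ALS0006",8.38636488339013,45
"ALS0006",11.3863648833901,47
"ALS0006",14.3863648833901,44
"ALS0007",4.63661086947212,45
"ALS0007",7.63661086947212,44
"ALS0007",10.6366108694721,35
"ALS0007",13.6366108694721,24
"ALS0007",16.6366108694721,10
"ALS0008",4.76518230895916,44
"ALS0008",7.76518230895916,41
"ALS0008",10.7651823089592,40
"ALS0008",13.7651823089592,34
"ALS0008",16.7651823089592,29
"ALS0009",7.21978031481739,46
"ALS0009",10.2197803148174,41
"ALS0009",13.2197803148174,42
"ALS0009",16.2197803148174,36
"ALS0009",19.2197803148174,35
"ALS0010",0.5,48
"ALS0010",3.5,45
"ALS0010",6.5,48
"ALS0010",9.5,44
"ALS0010",12.5,46
"ALS0011",7.4696638529091,48
"ALS0011",10.4696638529091,44
"ALS0011",13.4696638529091,47
"ALS0011",16.4696638529091,40
"ALS0011",19.4696638529091,34
"ALS0012",18.5758305745403,40
"ALS0012",21.5758305745403,37
"ALS0012",24.5758305745403,34
"ALS0012",27.5758305745403,34
"ALS0012",30.5758305745403,30
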