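"patient_id","group","nfl_pg_ml","log10_nfl","laboratory","t_sampling_months"
"ALS0001","ALS",20791.1351089512,4.31787820063962,"A",16.8406673933025
"ALS0002","ALS",4018.91775647839,3.6041091188387,"A",10.600415243172
"ALS0003","ALS",4356.45428386265,3.63913316095695,"B",5.29967653404158
"ALS0004","ALS",9327.73792946344,3.96977633572253,"A",25.3885889436607
"ALS0005","ALS",8658.55480868236,3.93744541037867,"A",14.0339060060756
"ALS0006","ALS",4497.71128397618,3.65299157386521,"A",8.38636488339013
"ALS0007","ALS",5093.04453335251,3.70697747364421,"A",10.6366108694721
"ALS0008","ALS",5443.07113962695,3.7358440104783,"A",10.7651823089592
"ALS0009","ALS",5530.33185965028,3.74275119287622,"B",13.2197803148174
"ALS0010","ALS",4572.32550867571,3.66013714070608,"A",4.09163810008615
"ALS0011","ALS",4146.95329950284,3.61772914462796,"A",13.4696638529091
"ALS0012","ALS",6536.66675824552,3.8153563450326,"A",24.5758305745403
"Cd001","disease_control",5451.84096441554,3.73654317854852,"B",NA
"Cd002","disease_control",774.263595789456,2.88888884015023,"B",NA
"Cd003","disease_control",1038.77032272892,3.01651953350715,"A",NA
"Cd004","disease_control",673.098140840212,2.82807839099657,"A",NA
"Cd005","disease_control",1296.28499715105,3.11270049465411,"B",NA
"Cd006","disease_control",2151.61456846883,3.33276447620481,"A",NA
"Cm001","mimic",1002.035162278,3.00088296156653,"A",NA
"Cm002","mimic",2977.28194872896,3.47381996430041,"B",NA
"Cm003","mimic",1016.22291013333,3.00698898159212,"A",NA
"Cn001","non_neurological",273.940493636547,2.43765623401758,"A",NA
"Cn002","non_neurological",300.623522134185,2.47802295873064,"A",NA
"Cn003","non_neurological",1155.40577567385,3.0627345341739,"A",NA
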