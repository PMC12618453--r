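"protocol","mode_or_ratio","strain_or_stretch_f","stretch_n","channel","stress_kPa"
"shear_fs","fs",0,NA,"sigma_fs",0
"shear_fs","fs",0.125,NA,"sigma_fs",0.116110253288731
"shear_fs","fs",0.25,NA,"sigma_fs",0.565771361247806
"shear_fs","fs",0.375,NA,"sigma_fs",1.83247641867326
"shear_fs","fs",0.5,NA,"sigma_fs",6.03973249402516
"shear_fn","fn",0,NA,"sigma_fn",0
"shear_fn","fn",0.125,NA,"sigma_fn",0.0536548211847438
"shear_fn","fn",0.25,NA,"sigma_fn",0.437832369721016
"shear_fn","fn",0.375,NA,"sigma_fn",1.63275160155354
"shear_fn","fn",0.5,NA,"sigma_fn",5.7581252912034
"shear_sf","sf",0,NA,"sigma_sf",0
"shear_sf","sf",0.125,NA,"sigma_sf",0.102713244603987
"shear_sf","sf",0.25,NA,"sigma_sf",0.45000149152679
"shear_sf","sf",0.375,NA,"sigma_sf",1.28668575461972
"shear_sf","sf",0.5,NA,"sigma_sf",2.85810720282176
"shear_sn","sn",0,NA,"sigma_sn",0
"shear_sn","sn",0.125,NA,"sigma_sn",0.0402578125
"shear_sn","sn",0.25,NA,"sigma_sn",0.3220625
"shear_sn","sn",0.375,NA,"sigma_sn",1.0869609375
"shear_sn","sn",0.5,NA,"sigma_sn",2.5765
"shear_nf","nf",0,NA,"sigma_nf",0
"shear_nf","nf",0.125,NA,"sigma_nf",0.0512445151770344
"shear_nf","nf",0.25,NA,"sigma_nf",0.411296226832643
"shear_nf","nf",0.375,NA,"sigma_nf",1.40853429330732
"shear_nf","nf",0.5,NA,"sigma_nf",3.48592268700907
"shear_ns","ns",0,NA,"sigma_ns",0
"shear_ns","ns",0.125,NA,"sigma_ns",0.0512445151770344
"shear_ns","ns",0.25,NA,"sigma_ns",0.411296226832643
"shear_ns","ns",0.375,NA,"sigma_ns",1.40853429330732
"shear_ns","ns",0.5,NA,"sigma_ns",3.48592268700907
"biaxial_1:1","1:1",1,1,"sigma_ff",0
"biaxial_1:1","1:1",1.025,1.025,"sigma_ff",0.406404399662579
"biaxial_1:1","1:1",1.05,1.05,"sigma_ff",1.15014871417492
"biaxial_1:1","1:1",1.075,1.075,"sigma_ff",2.68484931108457
"biaxial_1:1","1:1",1.1,1.1,"sigma_ff",5.92739082127647
"biaxial_1:1","1:1",1,1,"sigma_nn",0
"biaxial_1:1","1:1",1.025,1.025,"sigma_nn",0.325387183410293
"biaxial_1:1","1:1",1.05,1.05,"sigma_nn",0.851201455816421
"biaxial_1:1","1:1",1.075,1.075,"sigma_nn",1.75788156028761
"biaxial_1:1","1:1",1.1,1.1,"sigma_nn",3.25100258441204
"biaxial_1:0.5","1:0.5",1,1,"sigma_ff",0
"biaxial_1:0.5","1:0.5",1.025,1.0125,"sigma_ff",0.394267976095194
"biaxial_1:0.5","1:0.5",1.05,1.025,"sigma_ff",1.0510327280436
"biaxial_1:0.5","1:0.5",1.075,1.0375,"sigma_ff",2.34263111420261
"biaxial_1:0.5","1:0.5",1.1,1.05,"sigma_ff",5.09592761518965
"biaxial_1:0.5","1:0.5",1,1,"sigma_nn",0
"biaxial_1:0.5","1:0.5",1.025,1.0125,"sigma_nn",0.154369477117528
"biaxial_1:0.5","1:0.5",1.05,1.025,"sigma_nn",0.375102991074473
"biaxial_1:0.5","1:0.5",1.075,1.0375,"sigma_nn",0.721872516538327
"biaxial_1:0.5","1:0.5",1.1,1.05,"sigma_nn",1.25730613749488
"biaxial_1:0.75","1:0.75",1,1,"sigma_ff",0
"biaxial_1:0.75","1:0.75",1.025,1.01875,"sigma_ff",0.399474182560842
"biaxial_1:0.75","1:0.75",1.05,1.0375,"sigma_ff",1.09352500944312
"biaxial_1:0.75","1:0.75",1.075,1.05625,"sigma_ff",2.48920042171775
"biaxial_1:0.75","1:0.75",1.1,1.075,"sigma_ff",5.45156991162739
"biaxial_1:0.75","1:0.75",1,1,"sigma_nn",0
"biaxial_1:0.75","1:0.75",1.025,1.01875,"sigma_nn",0.237069196749279
"biaxial_1:0.75","1:0.75",1.05,1.0375,"sigma_nn",0.594492089619239
"biaxial_1:0.75","1:0.75",1.075,1.05625,"sigma_nn",1.17904351600307
"biaxial_1:0.75","1:0.75",1.1,1.075,"sigma_nn",2.10665361933456
"biaxial_0.5:1","0.5:1",1,1,"sigma_ff",0
"biaxial_0.5:1","0.5:1",1.0125,1.025,"sigma_ff",0.187416135187928
"biaxial_0.5:1","0.5:1",1.025,1.05,"sigma_ff",0.45612020732676
"biaxial_0.5:1","0.5:1",1.0375,1.075,"sigma_ff",0.883088206876957
"biaxial_0.5:1","0.5:1",1.05,1.1,"sigma_ff",1.55625339585338
"biaxial_0.5:1","0.5:1",1,1,"sigma_nn",0
"biaxial_0.5:1","0.5:1",1.0125,1.025,"sigma_nn",0.313250759842907
"biaxial_0.5:1","0.5:1",1.025,1.05,"sigma_nn",0.752085469685105
"biaxial_0.5:1","0.5:1",1.0375,1.075,"sigma_nn",1.41566336340565
"biaxial_0.5:1","0.5:1",1.05,1.1,"sigma_nn",2.41953937832523
"biaxial_0.75:1","0.75:1",1,1,"sigma_ff",0
"biaxial_0.75:1","0.75:1",1.01875,1.025,"sigma_ff",0.291291991100601
"biaxial_0.75:1","0.75:1",1.0375,1.05,"sigma_ff",0.755707779957868
"biaxial_0.75:1","0.75:1",1.05625,1.075,"sigma_ff",1.57988156854407
"biaxial_0.75:1","0.75:1",1.075,1.1,"sigma_ff",3.03362137013152
"biaxial_0.75:1","0.75:1",1,1,"sigma_nn",0
"biaxial_0.75:1","0.75:1",1.01875,1.025,"sigma_nn",0.318456966308555
"biaxial_0.75:1","0.75:1",1.0375,1.05,"sigma_nn",0.79457775108462
"biaxial_0.75:1","0.75:1",1.05625,1.075,"sigma_nn",1.5622326709208
"biaxial_0.75:1","0.75:1",1.075,1.1,"sigma_nn",2.77518167476296
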