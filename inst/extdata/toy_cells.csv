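cell_id,x_um,y_um,slide_id,sample_id,condition
toy_c1,10.5,12.25,sl1,s1,control
toy_c2,35.0,14.75,sl1,s1,control
toy_c3,22.5,40.0,sl1,s1,control
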