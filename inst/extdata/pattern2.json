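{"grid_shape":[40,40,17],"spacing":[1,1,1],"dt":2,"n_frames":30,"segments":[{"start_mm":[4,20,8],"end_mm":[12,20,8],"radius_mm":1.5,"velocity_mm_s":10,"inlet_arrival_s":4,"enhancement":1,"static":false,"name":"proximal"},{"start_mm":[12,20,8],"end_mm":[16,20,8],"radius_mm":1.5,"velocity_mm_s":10,"inlet_arrival_s":4.8,"enhancement":0.4,"static":false,"name":"thrombus"},{"start_mm":[16,20,8],"end_mm":[20,20,8],"radius_mm":1.5,"velocity_mm_s":10,"inlet_arrival_s":5.2,"enhancement":1,"static":false,"name":"mother"},{"start_mm":[20,20,8],"end_mm":[34,30,8],"radius_mm":1.5,"velocity_mm_s":-5,"inlet_arrival_s":5,"enhancement":1,"static":false,"name":"daughter_a"},{"start_mm":[20,20,8],"end_mm":[34,10,8],"radius_mm":1.5,"velocity_mm_s":-5,"inlet_arrival_s":5,"enhancement":1,"static":false,"name":"daughter_b"}],"bolus":{"amplitude_hu":400,"t_peak_s":6,"shape_alpha":3},"noise_sigma":5,"background_hu":40,"seed":12}
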