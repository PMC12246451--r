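table,key,value
voltages,200kV,200
voltages,80kV,80
apertures,40um,27.42
apertures,30um,20.52
apertures,20um,13.52
apertures,10um,6.02
magnifications,3e7,80
magnifications,1.5e7,160
camera_lengths,8,12.12
camera_lengths,10,15.2
camera_lengths,12,18.2
camera_lengths,15,22.7
camera_lengths,20,30.3
camera_lengths,25,37.9
camera_lengths,30,45.5
detector,n_pixels,192
detector,pitch_um,100
detector,binnings,1;2;4;8;16;24;48
detector,paar_mrad,120
detector,dtheta_mrad,0.83125
detector,dtheta_at_nominal_cl,8
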