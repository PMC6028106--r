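quantity,adult,aged,unit
cortical_thickness,1.03,0.87,mm
layer1_thickness,0.103,0.083,mm
total_synapse_density,1.40,1.17,per_um3
asym_density,1.23,1.07,per_um3
sym_density,0.15,0.08,per_um3
ei_ratio,0.123,0.078,ratio
mean_diameter,377.8,427.7,nm
lognormal_center,287.5,305.1,nm
lognormal_amplitude,7.27,4.9,percent
lognormal_width,0.33,0.47,log_units
perforated_synapses,3.81,8.1,percent
axon_length_density,8.15,10.27,um_per_um3
dendrite_length_density,1.37,1.53,um_per_um3
synapses_per_um_axon,0.173,0.116,per_um
synapses_per_um_dendrite,1.03,0.776,per_um
um_axon_per_synapse,5.82,8.62,um
vesicle_density,1847,2225,per_um3
donut_mitochondria,1,8,count
mitochondria_total,570,611,count
mito_volume_fraction,9.8,9.5,percent
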