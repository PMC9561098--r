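label,mean_mmHg,sd_mmHg,n
contoured_foam,55,9.524295,8
air_cell,42,9.148018,10
gel_foam,48.5,12.686388,12
visco_foam,60.2,14.097857,9
hybrid_foam_gel,51.3,10.257863,6
flat_foam,66.8,12.955504,5
contoured_gel,45.9,11.462448,7
dry_flotation,38.4,8.346674,15
segmented_air,57.6,11.52,4
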