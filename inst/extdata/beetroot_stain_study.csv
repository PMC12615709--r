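organism,dye_role,sharpness,entropy,contrast,snr,edge_intensity
A. flavus,test,109.19,6.47,53.9,2.46,0.0053
A. flavus,standard,112.4,6.94,82.11,1.95,0.0034
A. fumigatus,test,66.23,6.38,78.58,2.05,0.0077
A. fumigatus,standard,57.06,6.1,80.83,2.16,0.0039
A. niger,test,71.12,7.22,54.66,2.56,0.0101
A. niger,standard,111.41,7,61.58,2.79,0.0114
Cryptococcus spp.,test,62.95,6.34,62.15,2.39,0.0039
Cryptococcus spp.,standard,119,7.34,46.04,2.91,0.0295
Rhizopus spp.,test,57.65,6.88,73.43,1.88,0.0103
Rhizopus spp.,standard,59.21,7.35,75.36,2.07,0.0058
Trichophyton spp.,test,122.76,7.28,69,2.27,0.0537
Trichophyton spp.,standard,78.35,7.11,70.45,2.11,0.0053
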