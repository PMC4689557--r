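"oligo","strand","pos5","dinucleotide","delta_p_ppm"
"Oligo 4",1,2,"GpC",-4.023
"Oligo 4",1,3,"CpA",-4.183
"Oligo 4",1,4,"ApC",-4.169
"Oligo 4",1,5,"CpG",-4.281
"Oligo 4",1,6,"GpT",-4.072
"Oligo 4",1,7,"TpA",-4.255
"Oligo 4",1,8,"ApC",-4.181
"Oligo 4",1,9,"CpG",-4.205
"Oligo 4",1,10,"GpC",-4.001
"Oligo 4",2,14,"GpC",-4.008
"Oligo 4",2,15,"CpG",-4.242
"Oligo 4",2,16,"GpT",-4.153
"Oligo 4",2,17,"TpA",-4.287
"Oligo 4",2,18,"ApC",-4.077
"Oligo 4",2,19,"CpG",-4.188
"Oligo 4",2,20,"GpT",-4.119
"Oligo 4",2,21,"TpG",-4.167
"Oligo 4",2,22,"GpC",-3.977
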