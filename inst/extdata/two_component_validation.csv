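mixture,component,true_ppm,predicted_ppm
30/70,2-butanone,30,33
30/70,1-propanol,70,75
30/70,isoprene,0,2
30/70,ethylbenzene,0,4
30/70,styrene,0,-6
30/70,hexanal,0,-8
50/50,2-butanone,50,46
50/50,1-propanol,50,53
50/50,isoprene,0,0
50/50,ethylbenzene,0,-1
50/50,styrene,0,-2
50/50,hexanal,0,4
70/30,2-butanone,70,71
70/30,1-propanol,30,25
70/30,isoprene,0,-3
70/30,ethylbenzene,0,-1
70/30,styrene,0,4
70/30,hexanal,0,3
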