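joint,model,specimen,pct_body_mass
hip,min,Carnegie,9.05
hip,min,Sue,9.10
hip,min,Stan,12.3
hip,min,MOR,11.9
hip,min,Jane,13.2
hip,max,Carnegie,8.79
hip,max,Sue,10.7
hip,max,Stan,15.1
hip,max,MOR,13.9
hip,max,Jane,17.6
knee,min,Carnegie,4.10
knee,min,Sue,4.40
knee,min,Stan,5.68
knee,min,MOR,5.76
knee,min,Jane,4.94
knee,max,Carnegie,3.29
knee,max,Sue,4.80
knee,max,Stan,7.07
knee,max,MOR,6.84
knee,max,Jane,7.27
ankle,min,Carnegie,2.33
ankle,min,Sue,1.90
ankle,min,Stan,2.52
ankle,min,MOR,2.42
ankle,min,Jane,2.46
ankle,max,Carnegie,2.55
ankle,max,Sue,2.00
ankle,max,Stan,3.22
ankle,max,MOR,2.99
ankle,max,Jane,3.93
total,min,Carnegie,15.5
total,min,Sue,15.4
total,min,Stan,20.5
total,min,MOR,20.1
total,min,Jane,20.6
total,max,Carnegie,14.6
total,max,Sue,17.6
total,max,Stan,25.4
total,max,MOR,23.7
total,max,Jane,28.8
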