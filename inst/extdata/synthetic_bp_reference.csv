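"sex","age","height_low","height_high","sbp90","dbp90"
"female",6,75.5,100.5,101.65,63.075
"female",6,100.5,110.5,103.6,64
"female",6,110.5,120.5,103.6,63.9
"female",6,120.5,130.5,104.9,64.2
"female",6,130.5,155.5,105.75,64.625
"female",7,80.5,105.5,103.25,63.775
"female",7,105.5,115.5,104.8,64.2
"female",7,115.5,125.5,105.2,64.2
"female",7,125.5,135.5,106,65.2
"female",7,135.5,160.5,106.65,65.325
"female",8,85.5,110.5,104.75,63.975
"female",8,110.5,120.5,105.9,65.1
"female",8,120.5,130.5,106.2,64.9
"female",8,130.5,140.5,106.7,65.6
"female",8,140.5,165.5,108.15,66.125
"female",9,90.5,115.5,105.65,64.675
"female",9,115.5,125.5,106.9,65.1
"female",9,125.5,135.5,107,65.4
"female",9,135.5,145.5,108,65.8
"female",9,145.5,170.5,109.25,66.525
"female",10,95.5,120.5,106.65,65.475
"female",10,120.5,130.5,107.8,65.9
"female",10,130.5,140.5,108,65.6
"female",10,140.5,150.5,109.1,66.4
"female",10,150.5,175.5,110.45,66.925
"female",11,100.5,125.5,107.75,65.375
"female",11,125.5,135.5,109,66.1
"female",11,135.5,145.5,109.2,66.8
"female",11,145.5,155.5,110.3,66.7
"female",11,155.5,180.5,111.05,67.425
"female",12,105.5,130.5,109.25,65.975
"female",12,130.5,140.5,110,66.7
"female",12,140.5,150.5,110.5,66.9
"female",12,150.5,160.5,111,66.8
"female",12,160.5,185.5,112.45,67.525
"female",13,110.5,135.5,110.35,66.775
"female",13,135.5,145.5,111,67.3
"female",13,145.5,155.5,111.9,67.5
"female",13,155.5,165.5,112.9,68.1
"female",13,165.5,190.5,113.75,68.425
"female",14,115.5,140.5,110.75,67.475
"female",14,140.5,150.5,112.2,67.6
"female",14,150.5,160.5,112.2,67.9
"female",14,160.5,170.5,113.3,68.3
"female",14,170.5,195.5,113.65,68.925
"female",15,120.5,145.5,112.45,67.775
"female",15,145.5,155.5,113.5,68
"female",15,155.5,165.5,113.7,68.5
"female",15,165.5,175.5,114.1,68.6
"female",15,175.5,200.5,115.45,69.325
"female",16,125.5,150.5,113.35,68.375
"female",16,150.5,160.5,114.4,68.5
"female",16,160.5,170.5,115,69
"female",16,170.5,180.5,116.1,69.5
"female",16,180.5,205.5,116.85,69.825
"female",17,130.5,155.5,113.85,68.775
"female",17,155.5,165.5,115.6,69.4
"female",17,165.5,175.5,115.5,69.6
"female",17,175.5,185.5,116.5,69.8
"female",17,185.5,210.5,118.15,70.125
"male",6,76.5,101.5,103.65,63.175
"male",6,101.5,111.5,104.2,63.9
"male",6,111.5,121.5,104.6,64.2
"male",6,121.5,131.5,106.2,64.2
"male",6,131.5,156.5,106.75,65.225
"male",7,82.1,107.1,104.35,63.675
"male",7,107.1,117.1,105.1,64.3
"male",7,117.1,127.1,106.1,64.5
"male",7,127.1,137.1,106.8,64.7
"male",7,137.1,162.1,108.45,65.325
"male",8,87.7,112.7,105.75,64.375
"male",8,112.7,122.7,107.2,64.7
"male",8,122.7,132.7,107.5,64.7
"male",8,132.7,142.7,108.2,65.4
"male",8,142.7,167.7,108.45,65.825
"male",9,93.3,118.3,107.05,64.775
"male",9,118.3,128.3,107.5,65.1
"male",9,128.3,138.3,108.2,65.7
"male",9,138.3,148.3,108.6,65.6
"male",9,148.3,173.3,109.85,66.125
"male",10,98.9,123.9,108.15,65.475
"male",10,123.9,133.9,108.5,66
"male",10,133.9,143.9,109.5,65.9
"male",10,143.9,153.9,109.9,65.8
"male",10,153.9,178.9,111.15,67.325
"male",11,104.5,129.5,109.05,65.775
"male",11,129.5,139.5,110.1,66.1
"male",11,139.5,149.5,110.5,66.2
"male",11,149.5,159.5,111.3,67
"male",11,159.5,184.5,112.15,67.625
"male",12,110.1,135.1,109.85,66.175
"male",12,135.1,145.1,110.6,66.6
"male",12,145.1,155.1,111.8,66.9
"male",12,155.1,165.1,112.2,67.1
"male",12,165.1,190.1,112.75,68.225
"male",13,115.7,140.7,110.95,66.075
"male",13,140.7,150.7,111.6,67.1
"male",13,150.7,160.7,112.8,67.6
"male",13,160.7,170.7,113.4,67.8
"male",13,170.7,195.7,114.05,68.325
"male",14,121.3,146.3,112.35,67.375
"male",14,146.3,156.3,112.8,67.7
"male",14,156.3,166.3,114.1,67.8
"male",14,166.3,176.3,114.4,68.5
"male",14,176.3,201.3,115.65,68.425
"male",15,126.9,151.9,113.05,67.775
"male",15,151.9,161.9,114.2,68.2
"male",15,161.9,171.9,114.9,68.5
"male",15,171.9,181.9,115.8,68.9
"male",15,181.9,206.9,116.55,69.525
"male",16,132.5,157.5,113.65,68.075
"male",16,157.5,167.5,115.6,68.6
"male",16,167.5,177.5,116.1,69.2
"male",16,177.5,187.5,116.5,69.6
"male",16,187.5,212.5,117.95,69.925
"male",17,138.1,163.1,115.35,68.775
"male",17,163.1,173.1,116.1,69
"male",17,173.1,183.1,117,70
"male",17,183.1,193.1,117.4,69.8
"male",17,193.1,218.1,118.65,70.525
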