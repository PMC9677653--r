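perspective,age,strategy,ly,qaly,lifetime_cost,cost_per_ly,icer
government,20,PD,9.85,6.43,90204,9158,NA
government,20,HD,11.84,8.19,132084,11156,23796
government,30,PD,8.42,5.53,76613,9099,NA
government,30,HD,10.37,7.22,114911,11081,22662
government,40,PD,6.71,4.46,60255,8980,NA
government,40,HD,8.36,5.91,91366,10929,21456
government,50,PD,5.40,3.63,47873,8865,NA
government,50,HD,6.80,4.87,73243,10771,20460
government,60,PD,4.32,2.94,37837,8759,NA
government,60,HD,5.49,3.99,58243,10609,19434
societal,20,PD,9.85,6.43,96355,9782,NA
societal,20,HD,11.84,8.19,166600,14071,39912
societal,30,PD,8.42,5.53,81713,9705,NA
societal,30,HD,10.37,7.22,144894,13972,37385
societal,40,PD,6.71,4.46,63993,9537,NA
societal,40,HD,8.36,5.91,115143,13773,35276
societal,50,PD,5.40,3.63,50613,9373,NA
societal,50,HD,6.80,4.87,92251,13566,33579
societal,60,PD,4.32,2.94,39802,9213,NA
societal,60,HD,5.49,3.99,73311,13353,31913
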