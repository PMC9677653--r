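{"PD":{"shape":1.03952666803679,"scale":32.9095356774087,"coefficients":{"age":0.0370644860488149,"age2":-0.190366652854238,"age3":0.143795647448633},"chronic_hr":4.57952560427918,"stratum":"PD"},"HD":{"shape":3.98128234371003,"scale":19.920396074867,"coefficients":{"age":0.0282233140048786,"age2":-0.13292629265096,"age3":0.0973428035335377},"chronic_hr":5,"stratum":"HD"}}
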