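family,group,a,b,asymptote
exponential,L,0.5357,0.2667,NA
exponential,XL,0.6602,0.2645,NA
logistic,L,0.3718,0.2885,70
logistic,XL,0.4777,0.284,70
power,L,1.26,NA,NA
power,XL,1.27,NA,NA
gompertz,L,13.8,0.1823,70
gompertz,XL,12.95,0.1898,70
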