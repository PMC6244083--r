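# Photophysical data for Prodan (P) and Nile Red (NR) in the five reference
# solvents: toluene (t), dichloromethane (d), acetonitrile (a), methanol (m),
# water (w). quantum_yield is a fraction; tau_ns fluorescence lifetime in ns
# (metadata only); lambda_em_max / lambda_abs_max in nm; epsilon in 1/(M cm).
probe,solvent,quantum_yield,tau_ns,lambda_em_max,lambda_abs_max,epsilon
P,t,0.56,2.21,414,348,18400
P,d,0.98,3.20,438,353,24600
P,a,0.95,3.30,456,350,21400
P,m,0.77,2.57,501,360,19500
P,w,0.25,0.98,524,359,13200
NR,t,0.80,3.97,566,535,29500
NR,d,0.78,4.52,600,538,35500
NR,a,0.76,4.63,613,556,38600
NR,m,0.40,2.76,633,526,32800
NR,w,0.005,0.55,660,588,14400
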