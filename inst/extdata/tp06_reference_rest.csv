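# synthetic reference: TP06 quiescent state after 50 s,
# scipy LSODA rtol=1e-8; tools/make_reference_trace.py
V,m,h,j,d,f,f2,fCass,r,s,xr1,xr2,xs,Na_i,K_i,Ca_i,Ca_sr,Ca_ss,R_bar
-86.504491,0.0013077533,0.77814543,0.77813938,2.8451954e-05,0.99992519,0.99957305,0.99999822,1.9541096e-08,0.99999833,0.00017624216,0.48442679,0.0029537351,6.7452909,139.6561,3.495633e-05,0.42471425,8.6181394e-05,0.99815027
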