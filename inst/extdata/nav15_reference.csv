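feature,units,exp_mean,exp_sd
activation_V12,mV,-34.5,1.5
activation_k,mV,-7.2,0.6
availability_V12,mV,-89.1,1.6
availability_k,mV,5.5,0.4
repriming_tau_-120,ms,5.1,0.9
repriming_tau_-110,ms,12.5,2.1
repriming_tau_-100,ms,26.1,3.8
repriming_tau_-90,ms,47.9,3.4
slow_recovery_tau1,ms,5.1,0.9
slow_recovery_frac1,%,78,NA
slow_recovery_tau2,ms,596.3,NA
slow_recovery_frac2,%,22,NA
slow_onset_tau,s,1.79,0.11
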