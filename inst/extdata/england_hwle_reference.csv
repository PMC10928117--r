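model,group,hwle,nonhw,le
age_only,all,9.03,22.59,31.62
sex,female,8.25,25.11,33.36
sex,male,9.94,19.78,29.73
oa,yes,7.29,25.01,32.30
oa,no,9.50,21.80,31.30
mh,yes,6.87,22.02,28.89
mh,no,9.76,23.24,33.01
obese,yes,8.44,22.94,31.38
obese,no,9.31,22.42,31.73
pain,yes,6.54,23.33,29.87
pain,no,9.79,22.62,32.41
inactive,yes,7.67,20.69,28.36
inactive,no,9.62,26.39,36.01
noauto,yes,7.67,23.54,31.21
noauto,no,9.50,22.26,31.76
nosupport,yes,7.86,23.37,31.24
nosupport,no,9.52,22.25,31.78
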