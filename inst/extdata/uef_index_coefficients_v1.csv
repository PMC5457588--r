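# Published multivariable ordinal logistic model for the UEF categorical
# index (version 1). Cumulative-logit parameterisation
# P(frailty <= k) = logistic(alpha_k + x' beta); moment enters as its
# natural logarithm; sex coded female = 1.
term,estimate,se,unit
intercept_nonfrail,-2.6304,2.0702,logit
intercept_prefrail,1.5140,2.0759,logit
speed,0.0025,0.0010,deg/s
flexibility,0.0207,0.0069,deg
log_moment,0.7176,0.3278,log(Nm)
speed_variability,-0.0441,0.0206,%
speed_reduction,-0.0342,0.0153,%
flexion_number,0.0647,0.0284,count
sex_female,0.1214,0.1570,indicator
age,-0.0206,0.0158,year
bmi,-0.0611,0.0284,kg/m2
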