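# Published basal-haplogroup age table used as test expectations: per clade,
# N / rho / sigma / age / age-sigma under the complete-genome and synonymous
# clocks (shared N) and the HVS-transition clock (own N). NA = not printed.
published_ages <- function() {
  txt <- "
hap,N,rho_c,sig_c,age_c,agesig_c,rho_s,sig_s,age_s,agesig_s,N_h,rho_h,sig_h,age_h,agesig_h
M24,9,7.89,1.64,20.39,4.23,2.78,1.07,21.90,8.45,37,0.84,0.73,15.79,13.84
M45,16,9.50,1.47,24.56,3.79,3.88,0.82,30.55,6.44,19,2.32,0.96,43.64,18.02
M54,12,9.00,2.22,23.26,5.73,3.75,1.53,29.56,12.06,22,2.32,1.00,43.69,18.90
M54a,11,7.36,1.95,19.03,5.05,3.09,1.33,24.37,10.53,20,1.45,0.45,27.32,8.58
M49,32,9.19,1.52,23.75,3.93,3.00,0.77,23.65,6.07,NA,NA,NA,NA,NA
M55,10,6.20,1.50,16.03,3.87,1.30,0.56,10.25,4.39,37,0.89,0.52,16.81,9.81
M55a,7,3.00,1.08,7.75,2.79,1.43,0.73,11.26,5.74,NA,NA,NA,NA,NA
M55b,3,0.33,0.33,0.86,0.86,NA,NA,NA,NA,NA,NA,NA,NA,NA
M58,4,17.00,2.62,43.94,6.78,3.75,1.25,29.56,9.85,11,4.73,1.44,89.09,27.09
M72,6,5.83,1.26,15.08,3.25,1.17,0.60,9.20,4.74,22,1.54,0.57,29.12,10.70
M83,5,13.40,1.99,34.64,5.14,5.80,1.25,45.73,9.85,40,1.00,0.38,18.84,7.21
M84,14,5.64,1.43,14.59,3.69,0.79,0.33,6.19,2.58,58,0.47,0.19,8.77,3.60
M84a,11,4.00,1.34,10.34,3.45,0.64,0.30,5.02,2.38,NA,NA,NA,NA,NA
M84b,3,0.67,0.67,1.72,1.72,NA,NA,NA,NA,NA,NA,NA,NA,NA
M90,7,11.29,2.26,29.17,5.85,4.14,1.41,32.66,11.09,27,0.26,0.10,4.89,1.85
M91,10,15.30,2.45,39.55,6.33,7.70,1.88,60.71,14.85,17,1.88,0.91,35.47,17.17
R31,9,21.78,2.56,56.30,6.61,8.22,1.60,64.82,12.63,74,3.76,0.95,70.80,17.84
M51,24,12.33,2.01,31.88,5.18,3.08,0.75,24.31,5.91,25,1.88,0.68,35.43,12.72
M63,8,9.88,2.35,25.53,6.07,5.50,1.78,43.36,14.01,13,1.46,0.77,27.55,14.42
N21,14,6.50,1.46,16.80,3.77,1.93,0.63,15.20,5.01,122,1.50,0.59,28.11,11.12"
  read.csv(text = txt, stringsAsFactors = FALSE)
}
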