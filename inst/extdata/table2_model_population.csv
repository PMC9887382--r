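cohort,n,variable,level,count,percent,value
marina_sham,238,sex,female,159,66.8,
marina_sham,238,sex,male,79,33.2,
marina_sham,238,age_band,<65,11,4.6,
marina_sham,238,age_band,65-69,17,7.1,
marina_sham,238,age_band,70-74,50,21.0,
marina_sham,238,age_band,75-79,68,28.6,
marina_sham,238,age_band,80-84,64,26.9,
marina_sham,238,age_band,85+,26,10.9,
marina_sham,238,ethnicity,white,231,97.1,
marina_sham,238,ethnicity,not_white,7,2.9,
marina_sham,238,smoker,yes,130,54.6,
marina_sham,238,smoker,no_or_unknown,108,45.4,
marina_sham,238,va,mean,,,53.61
marina_sham,238,va,sd,,,14.06
marina_sham,238,va,median,,,56.0
marina_sham,238,va,min,,,3.0
marina_sham,238,va,max,,,84.0
marina_sham,238,va_ge70,yes,22,9.2,
marina_sham,238,va_ge70,no,216,90.8,
marina_sham,238,va_le20,yes,4,1.7,
marina_sham,238,va_le20,no,234,98.3,
marina_sham,238,va_lt25,yes,9,3.8,
marina_sham,238,va_lt25,no,229,96.2,
meh_matched,215,sex,female,128,59.5,
meh_matched,215,sex,male,87,40.5,
meh_matched,215,age_band,<65,9,4.2,
meh_matched,215,age_band,65-69,19,8.8,
meh_matched,215,age_band,70-74,37,17.2,
meh_matched,215,age_band,75-79,58,27.0,
meh_matched,215,age_band,80-84,60,27.9,
meh_matched,215,age_band,85+,32,14.9,
meh_matched,215,ethnicity,white,97,45.1,
meh_matched,215,ethnicity,not_white,118,54.9,
meh_matched,215,smoker,yes,110,51.2,
meh_matched,215,smoker,no_or_unknown,105,48.8,
meh_matched,215,va,mean,,,52.92
meh_matched,215,va,sd,,,14.45
meh_matched,215,va,median,,,55.0
meh_matched,215,va,min,,,0
meh_matched,215,va,max,,,86.0
meh_matched,215,va_ge70,yes,16,7.4,
meh_matched,215,va_ge70,no,199,92.6,
meh_matched,215,va_le20,yes,3,1.4,
meh_matched,215,va_le20,no,212,98.6,
meh_matched,215,va_lt25,yes,12,5.6,
meh_matched,215,va_lt25,no,203,94.4,
meh_unmatched,110,sex,female,73,66.4,
meh_unmatched,110,sex,male,37,33.6,
meh_unmatched,110,age_band,<65,6,5.5,
meh_unmatched,110,age_band,65-69,4,3.6,
meh_unmatched,110,age_band,70-74,14,12.7,
meh_unmatched,110,age_band,75-79,13,11.8,
meh_unmatched,110,age_band,80-84,20,18.2,
meh_unmatched,110,age_band,85+,53,48.2,
meh_unmatched,110,ethnicity,white,55,50.0,
meh_unmatched,110,ethnicity,not_white,55,50.0,
meh_unmatched,110,smoker,yes,55,50.0,
meh_unmatched,110,smoker,no_or_unknown,55,50.0,
meh_unmatched,110,va,mean,,,59.50
meh_unmatched,110,va,sd,,,18.36
meh_unmatched,110,va,median,,,70.0
meh_unmatched,110,va,min,,,11.0
meh_unmatched,110,va,max,,,85.0
meh_unmatched,110,va_ge70,yes,61,55.5,
meh_unmatched,110,va_ge70,no,49,44.5,
meh_unmatched,110,va_le20,yes,3,2.7,
meh_unmatched,110,va_le20,no,107,97.3,
meh_unmatched,110,va_lt25,yes,7,6.4,
meh_unmatched,110,va_lt25,no,103,93.6,
uhb_matched,44,sex,female,32,72.7,
uhb_matched,44,sex,male,12,27.3,
uhb_matched,44,age_band,<65,2,4.5,
uhb_matched,44,age_band,65-69,1,2.3,
uhb_matched,44,age_band,70-74,4,9.1,
uhb_matched,44,age_band,75-79,4,9.1,
uhb_matched,44,age_band,80-84,19,43.2,
uhb_matched,44,age_band,85+,14,31.8,
uhb_matched,44,ethnicity,white,39,88.6,
uhb_matched,44,ethnicity,not_white,5,11.4,
uhb_matched,44,smoker,yes,33,75.0,
uhb_matched,44,smoker,no_or_unknown,11,25.0,
uhb_matched,44,va,mean,,,52.55
uhb_matched,44,va,sd,,,15.98
uhb_matched,44,va,median,,,55.0
uhb_matched,44,va,min,,,0
uhb_matched,44,va,max,,,76.0
uhb_matched,44,va_ge70,yes,8,18.2,
uhb_matched,44,va_ge70,no,36,81.8,
uhb_matched,44,va_le20,yes,1,2.3,
uhb_matched,44,va_le20,no,43,97.7,
uhb_matched,44,va_lt25,yes,1,2.3,
uhb_matched,44,va_lt25,no,43,97.7,
uhb_unmatched,7,sex,female,7,100.0,
uhb_unmatched,7,sex,male,0,0.0,
uhb_unmatched,7,age_band,<65,0,0.0,
uhb_unmatched,7,age_band,65-69,0,0.0,
uhb_unmatched,7,age_band,70-74,0,0.0,
uhb_unmatched,7,age_band,75-79,0,0.0,
uhb_unmatched,7,age_band,80-84,0,0.0,
uhb_unmatched,7,age_band,85+,7,100.0,
uhb_unmatched,7,ethnicity,white,6,85.7,
uhb_unmatched,7,ethnicity,not_white,1,14.3,
uhb_unmatched,7,smoker,yes,3,42.9,
uhb_unmatched,7,smoker,no_or_unknown,4,57.1,
uhb_unmatched,7,va,mean,,,40.57
uhb_unmatched,7,va,sd,,,20.98
uhb_unmatched,7,va,median,,,35.0
uhb_unmatched,7,va,min,,,11.0
uhb_unmatched,7,va,max,,,80.0
uhb_unmatched,7,va_ge70,yes,1,14.3,
uhb_unmatched,7,va_ge70,no,6,85.7,
uhb_unmatched,7,va_le20,yes,1,14.3,
uhb_unmatched,7,va_le20,no,6,85.7,
uhb_unmatched,7,va_lt25,yes,1,14.3,
uhb_unmatched,7,va_lt25,no,6,85.7,
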