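endpoint,variable,level,years_survived,percent
os,overall,overall,0,71.8
os,overall,overall,1,72.9
os,overall,overall,2,76.5
os,overall,overall,3,77.9
os,overall,overall,4,79.6
os,overall,overall,5,79.3
css,overall,overall,0,77.1
css,overall,overall,1,78.1
css,overall,overall,2,81.3
css,overall,overall,3,82.7
css,overall,overall,4,84.9
css,overall,overall,5,85.8
os,fnclcc_grade,I,0,90.5
os,fnclcc_grade,I,1,87.7
os,fnclcc_grade,I,2,87.1
os,fnclcc_grade,I,3,89.1
os,fnclcc_grade,I,4,85.4
os,fnclcc_grade,I,5,90.0
os,fnclcc_grade,III,0,53.8
os,fnclcc_grade,III,1,58.5
os,fnclcc_grade,III,2,66.2
os,fnclcc_grade,III,3,68.0
os,fnclcc_grade,III,4,71.5
os,fnclcc_grade,III,5,78.9
css,chemotherapy,no,0,80.6
css,chemotherapy,no,1,81.3
css,chemotherapy,no,2,83.8
css,chemotherapy,no,3,84.5
css,chemotherapy,no,4,86.5
css,chemotherapy,no,5,86.7
css,chemotherapy,yes,0,56.2
css,chemotherapy,yes,1,58.0
css,chemotherapy,yes,2,64.1
css,chemotherapy,yes,3,68.6
css,chemotherapy,yes,4,72.2
css,chemotherapy,yes,5,77.7
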