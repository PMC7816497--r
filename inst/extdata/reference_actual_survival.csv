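endpoint,years,percent
os,1,89.8
os,3,71.8
os,4,65.5
os,5,60.8
os,6,56.0
os,8,48.2
css,1,91.9
css,3,77.1
css,4,71.8
css,5,67.8
css,6,63.7
css,8,58.2
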