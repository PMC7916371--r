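spread,fm,threshold_db_spl,se,min,max
low,1440.5,64.4,6.9,52.1,79.0
low,1637,58.4,9.6,36.8,73.1
low,1898.5,46.5,8.8,16.6,59.8
low,2226,20.3,4.3,12.8,28.2
low,2619,44.6,13.9,23.8,77.0
low,3143,67.0,13.9,45.2,84.2
low,3798,77.2,18.2,12.3,88.1
medium,1440.5,66.2,9.2,41.5,82.5
medium,1637,58.4,13.9,11.2,77.7
medium,1898.5,45.9,7.9,22.8,65.6
medium,2226,23.1,7.3,12.4,36.7
medium,2619,45.7,13.8,23.4,70.2
medium,3143,67.3,12.6,46.0,86.3
medium,3798,80.8,12.1,43.1,90.0
high,1440.5,61.8,7.5,48.2,76.1
high,1637,48.4,9.9,19.8,63.6
high,1898.5,38.4,5.8,24.4,48.1
high,2226,22.6,5.5,13.8,35.3
high,2619,35.4,11.8,13.9,60.8
high,3143,45.7,10.9,24.3,62.2
high,3798,59.3,10.4,42.7,74.8
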