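{"n_sites":20,"n_sites_retained":14,"retained_site_pos":[100,200,300,400,500,600,700,800,900,1000,1100,1200,1300,1400],"n_peaks":10,"n_peaks_retained":6,"retained_peaks":["toyPeak01","toyPeak02","toyPeak03","toyPeak04","toyPeak05","toyPeak06"]}
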