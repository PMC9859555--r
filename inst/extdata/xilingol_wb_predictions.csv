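year,month,SM10,SM40,SM100,SM200
2022,4,15.12,52.35,94.11,164.44
2022,5,15.59,52.23,96.09,164.32
2022,6,15.91,51.57,98.81,164.15
2022,7,16.12,50.45,102.15,163.94
2022,8,14.94,47.35,105.22,163.71
2022,9,14.28,45.48,107.23,163.56
2022,10,13.76,44.12,108.58,163.47
2022,11,12.41,41.95,108.80,163.42
2022,12,12.68,42.66,108.14,163.47
2023,1,12.21,42.26,107.35,163.51
2023,2,12.16,42.73,106.09,163.59
2023,3,13.39,44.89,105.43,163.66
2023,4,14.05,45.63,106.09,163.63
2023,5,14.76,46.00,107.77,163.54
2023,6,15.17,45.49,110.40,163.38
2023,7,15.42,44.46,113.73,163.17
2023,8,14.18,41.26,116.81,162.94
2023,9,13.56,39.46,118.79,162.79
2023,10,12.98,38.02,120.09,162.70
2023,11,12.22,36.66,120.58,162.65
2023,12,12.08,36.50,120.43,162.65
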