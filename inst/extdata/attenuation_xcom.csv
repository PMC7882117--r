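# Mass attenuation coefficients (cm^2/g) vs photon energy (keV), transcribed
# from the NIST XCOM photon cross-section database (with coherent scattering).
# Sparse knots; the package interpolates log-log onto a 1-keV grid (10-150 keV).
# K-edges (iodine 33.17 keV, tin 29.20 keV) are represented by two-sided knots.
material,density_g_cm3,energy_kev,mu_over_rho
water,1.000,10,5.329
water,1.000,15,1.673
water,1.000,20,0.8096
water,1.000,30,0.3756
water,1.000,40,0.2683
water,1.000,50,0.2269
water,1.000,60,0.2059
water,1.000,80,0.1837
water,1.000,100,0.1707
water,1.000,150,0.1505
acrylic,1.190,10,3.357
acrylic,1.190,15,1.101
acrylic,1.190,20,0.5714
acrylic,1.190,30,0.3032
acrylic,1.190,40,0.2350
acrylic,1.190,50,0.2074
acrylic,1.190,60,0.1924
acrylic,1.190,80,0.1751
acrylic,1.190,100,0.1641
acrylic,1.190,150,0.1456
aluminum,2.699,10,26.23
aluminum,2.699,15,7.955
aluminum,2.699,20,3.441
aluminum,2.699,30,1.128
aluminum,2.699,40,0.5685
aluminum,2.699,50,0.3681
aluminum,2.699,60,0.2778
aluminum,2.699,80,0.2018
aluminum,2.699,100,0.1704
aluminum,2.699,150,0.1378
iodine,4.933,10,162.0
iodine,4.933,15,55.46
iodine,4.933,20,25.66
iodine,4.933,30,8.561
iodine,4.933,33.16,6.553
iodine,4.933,33.18,36.00
iodine,4.933,40,22.10
iodine,4.933,50,12.32
iodine,4.933,60,7.579
iodine,4.933,80,3.510
iodine,4.933,100,1.942
iodine,4.933,150,0.860
tin,7.310,10,140.9
tin,7.310,15,45.50
tin,7.310,20,21.30
tin,7.310,25,11.64
tin,7.310,29.19,7.760
tin,7.310,29.21,43.20
tin,7.310,40,19.22
tin,7.310,50,10.73
tin,7.310,60,6.640
tin,7.310,80,3.088
tin,7.310,100,1.720
tin,7.310,150,0.792
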