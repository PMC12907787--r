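material,density,e1_kev,mu1,e2_kev,mu2,e_check_kev,mu_check
water,1,40,0.2683,80,0.1837,70,0.1931
air,0.001205,40,3e-04,80,2e-04,70,0.000211
polyethylene,0.94,40,0.211946,80,0.17179,70,0.177658
acrylic,1.19,40,0.277238,80,0.208288,70,0.216775
bone,1.55,40,0.942666,80,0.335569,70,0.382858
fat,0.95,40,0.216436,80,0.169889,70,0.176155
aluminum,2.699,40,1.759396,80,0.57171,70,0.662671
steel,7.87,40,46.389153,80,6.789867,70,9.597901
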