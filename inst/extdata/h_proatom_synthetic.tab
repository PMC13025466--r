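# synthetic model hydrogen proatom density (Gaussian-shell model, not DFT)
# r_bohr   rho_e_per_bohr3
  0.0000  1.9312647597e-01
  0.1000  1.8966492385e-01
  0.2000  1.7967653450e-01
  0.3000  1.6427413823e-01
  0.4000  1.4507943373e-01
  0.5000  1.2393738331e-01
  0.6000  1.0262239215e-01
  0.7000  8.2600285561e-02
  0.8000  6.4887045765e-02
  0.9000  5.0014567480e-02
  1.0000  3.8086129215e-02
  1.1000  2.8887518833e-02
  1.2000  2.2016188309e-02
  1.3000  1.6997954340e-02
  1.4000  1.3373408956e-02
  1.5000  1.0749036361e-02
  1.6000  8.8174482772e-03
  1.7000  7.3558731075e-03
  1.8000  6.2126678457e-03
  1.9000  5.2897146572e-03
  2.0000  4.5257272500e-03
  2.1000  3.8828717458e-03
  2.2000  3.3372486337e-03
  2.3000  2.8727572349e-03
  2.4000  2.4774842312e-03
  2.5000  2.1417655722e-03
  2.6000  1.8572496993e-03
  2.7000  1.6165015637e-03
  2.8000  1.4128650833e-03
  2.9000  1.2404277060e-03
  3.0000  1.0940096713e-03
  3.1000  9.6914529815e-04
  3.2000  8.6204665375e-04
  3.3000  7.6955052306e-04
  3.4000  6.8905358753e-04
  3.5000  6.1844149910e-04
  3.6000  5.5601690454e-04
  3.7000  5.0043033406e-04
  3.8000  4.5061665160e-04
  3.9000  4.0573866897e-04
  4.0000  3.6513863078e-04
  4.1000  3.2829760050e-04
  4.2000  2.9480230667e-04
  4.3000  2.6431871478e-04
  4.4000  2.3657143944e-04
  4.5000  2.1132806720e-04
  4.6000  1.8838749223e-04
  4.7000  1.6757144453e-04
  4.8000  1.4871849489e-04
  4.9000  1.3167993294e-04
  5.0000  1.1631702573e-04
  5.1000  1.0249926541e-04
  5.2000  9.0103303484e-05
  5.3000  7.9012343425e-05
  5.4000  6.9115823917e-05
  5.5000  6.0309272804e-05
  5.6000  5.2494248575e-05
  5.7000  4.5578313858e-05
  5.8000  3.9475005606e-05
  5.9000  3.4103781215e-05
  6.0000  2.9389929910e-05
  6.1000  2.5264445600e-05
  6.2000  2.1663861871e-05
  6.3000  1.8530052562e-05
  6.4000  1.5810002911e-05
  6.5000  1.3455557000e-05
  6.6000  1.1423147418e-05
  6.7000  9.6735128751e-06
  6.8000  8.1714090777e-06
  6.9000  6.8853176595e-06
  7.0000  5.7871573457e-06
  7.1000  4.8520009038e-06
  7.2000  4.0578008198e-06
  7.3000  3.3851260543e-06
  7.4000  2.8169116850e-06
  7.5000  2.3382227530e-06
  7.6000  1.9360331877e-06
  7.7000  1.5990203009e-06
  7.8000  1.3173750115e-06
  7.9000  1.0826276859e-06
  8.0000  8.8748924883e-07
  8.1000  7.2570703995e-07
  8.2000  5.9193474873e-07
  8.3000  4.8161565853e-07
  8.4000  3.9087835811e-07
  8.5000  3.1644403680e-07
  8.6000  2.5554446019e-07
  8.7000  2.0584972391e-07
  8.8000  1.6540489995e-07
  8.9000  1.3257471947e-07
  9.0000  1.0599547526e-07
  9.1000  8.4533373325e-08
  9.2000  6.7248613891e-08
  9.3000  5.3364536080e-08
  9.4000  4.2241215160e-08
  9.5000  3.3352956096e-08
  9.6000  2.6269180475e-08
  9.7000  2.0638255300e-08
  9.8000  1.6173860780e-08
  9.9000  1.2643539926e-08
 10.0000  9.8591149900e-09
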