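# Lebedev-Laikov octahedral quadrature: orbit parameters (type, a, b, weight)
# weight is per-point, normalized so the rule's weights sum to 1.
# orbit types: 1=(1,0,0)x6  2=(1,1,0)/sqrt2 x12  3=(1,1,1)/sqrt3 x8
#              4=(a,a,b)x24  5=(a,b,0)x24  6=(a,b,c)x48
.lebedev_orbits <- list(
  "6" = rbind(
    c(1, 0.0000000000000000e+00, 0.0000000000000000e+00, 1.6666666666666666e-01)),
  "26" = rbind(
    c(3, 0.0000000000000000e+00, 0.0000000000000000e+00, 3.2142857142857140e-02),
    c(2, 0.0000000000000000e+00, 0.0000000000000000e+00, 3.8095238095238099e-02),
    c(1, 0.0000000000000000e+00, 0.0000000000000000e+00, 4.7619047619047623e-02)),
  "50" = rbind(
    c(1, 0.0000000000000000e+00, 0.0000000000000000e+00, 1.2698412698412700e-02),
    c(4, 3.0151134457776357e-01, 9.0453403373329089e-01, 2.0173335537918870e-02),
    c(3, 0.0000000000000000e+00, 0.0000000000000000e+00, 2.1093750000000001e-02),
    c(2, 0.0000000000000000e+00, 0.0000000000000000e+00, 2.2574955908289240e-02)),
  "110" = rbind(
    c(1, 0.0000000000000000e+00, 0.0000000000000000e+00, 3.8282704949371611e-03),
    c(4, 1.8511563534473621e-01, 9.6512403508659406e-01, 8.2117372831911097e-03),
    c(4, 3.9568947305594188e-01, 8.2876998125259227e-01, 9.5954713360709605e-03),
    c(5, 4.7836902881215021e-01, 0.0000000000000000e+00, 9.6949963616630268e-03),
    c(3, 0.0000000000000000e+00, 0.0000000000000000e+00, 9.7937375124875110e-03),
    c(4, 6.9042104838229224e-01, 2.1595729184584844e-01, 9.9428148911781013e-03)),
  "302" = rbind(
    c(1, 0.0000000000000000e+00, 0.0000000000000000e+00, 8.5459117251281483e-04),
    c(4, 9.6183085226147838e-02, 9.9070562137940810e-01, 2.3521014136891642e-03),
    c(5, 2.6441528870606629e-01, 0.0000000000000000e+00, 2.9823449631718041e-03),
    c(4, 2.2196452362941779e-01, 9.4945431722644313e-01, 3.1089531224136749e-03),
    c(6, 1.2335485325833270e-01, 4.1277240831685308e-01, 3.3923122050061698e-03),
    c(4, 3.5156403455701052e-01, 8.6764362454408339e-01, 3.4497884243058830e-03),
    c(6, 2.5100347517704652e-01, 5.4486773725807736e-01, 3.5715405542733870e-03),
    c(4, 4.7290541325810048e-01, 7.4345204298755574e-01, 3.5767296617433670e-03),
    c(3, 0.0000000000000000e+00, 0.0000000000000000e+00, 3.5991192850255709e-03),
    c(5, 5.7189558918789607e-01, 0.0000000000000000e+00, 3.6008209322164601e-03),
    c(4, 6.5663294102196124e-01, 3.7103417838482095e-01, 3.6048226014198819e-03),
    c(4, 7.0117664160895454e-01, 1.2923867271051442e-01, 3.6500458076772551e-03))
)
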