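# Idealized deoxynucleotide templates (heavy atoms, 5'-phosphate form).
# Frame: base plane = z=0, glycosidic N at origin, C1' along -x.
.nt_templates <- list(
  DA = {
    m <- rbind(c(-0.8956, -5.1804, -1.1949),
    c(0.4308, -5.5233, -1.7757),
    c(-1.0054, -5.5632, 0.3495),
    c(-1.3263, -3.6434, -1.2736),
    c(-2.6471, -3.2960, -0.8779),
    c(-2.7727, -1.7841, -0.7107),
    c(-1.9291, -1.3179, 0.3643),
    c(-2.3595, -0.9823, -1.9389),
    c(-3.3964, -0.9087, -2.9010),
    c(-2.0723, 0.3677, -1.3260),
    c(-1.4518, 0.0000, 0.0151),
    c(0.0000, 0.0000, 0.0000),
    c(0.8435, -1.0777, 0.0000),
    c(2.1103, -0.7150, 0.0000),
    c(2.0812, 0.6643, 0.0000),
    c(3.0949, 1.6368, 0.0000),
    c(4.4483, 1.3251, 0.0000),
    c(2.7377, 2.9416, 0.0000),
    c(1.4217, 3.2467, 0.0000),
    c(0.3652, 2.4070, 0.0000),
    c(0.7762, 1.1280, 0.0000))
    rownames(m) <- c("P", "OP1", "OP2", "O5'", "C5'", "C4'", "O4'", "C3'", "O3'", "C2'", "C1'", "N9", "C8", "N7", "C5", "C6", "N6", "N1", "C2", "N3", "C4")
    colnames(m) <- c("x","y","z")
    m
  },
  DC = {
    m <- rbind(c(-4.2503, 4.8857, -0.1487),
    c(-5.5709, 5.5711, -0.1197),
    c(-3.0872, 5.7909, -0.7550),
    c(-4.1763, 3.5205, -0.9764),
    c(-2.9318, 2.8419, -1.0734),
    c(-3.1534, 1.3440, -0.8598),
    c(-1.9488, 0.6247, -1.2010),
    c(-3.4851, 0.9979, 0.5970),
    c(-4.2838, -0.1906, 0.6639),
    c(-2.1322, 0.6735, 1.1835),
    c(-1.4575, -0.0000, -0.0042),
    c(0.0000, 0.0000, 0.0000),
    c(0.7000, 1.2115, 0.0000),
    c(0.1231, 2.2963, 0.0000),
    c(2.0765, 1.1715, 0.0000),
    c(2.6932, 0.0334, 0.0000),
    c(4.0606, 0.0687, 0.0000),
    c(1.9968, -1.2647, 0.0000),
    c(0.6669, -1.2069, 0.0000))
    rownames(m) <- c("P", "OP1", "OP2", "O5'", "C5'", "C4'", "O4'", "C3'", "O3'", "C2'", "C1'", "N1", "C2", "O2", "N3", "C4", "N4", "C5", "C6")
    colnames(m) <- c("x","y","z")
    m
  },
  DG = {
    m <- rbind(c(1.2488, 2.4364, 2.9582),
    c(0.8676, 3.6094, 2.1257),
    c(1.5654, 2.7449, 4.4920),
    c(0.2299, 1.2042, 3.0275),
    c(-1.1394, 1.4982, 3.2818),
    c(-2.0413, 0.7312, 2.3108),
    c(-1.7958, 1.1624, 0.9484),
    c(-1.8251, -0.7824, 2.3434),
    c(-2.7337, -1.4277, 3.2221),
    c(-2.0870, -1.1572, 0.9043),
    c(-1.4454, 0.0000, 0.1562),
    c(0.0000, 0.0000, 0.0000),
    c(0.7629, 1.1422, 0.0000),
    c(2.0569, 0.8913, 0.0000),
    c(2.1235, -0.4800, 0.0000),
    c(3.2740, -1.3575, 0.0000),
    c(4.4453, -0.9955, 0.0000),
    c(2.9139, -2.6959, 0.0000),
    c(1.6132, -3.1536, 0.0000),
    c(1.4528, -4.5007, 0.0000),
    c(0.5663, -2.3732, 0.0000),
    c(0.8704, -1.0536, 0.0000))
    rownames(m) <- c("P", "OP1", "OP2", "O5'", "C5'", "C4'", "O4'", "C3'", "O3'", "C2'", "C1'", "N9", "C8", "N7", "C5", "C6", "O6", "N1", "C2", "N2", "N3", "C4")
    colnames(m) <- c("x","y","z")
    m
  },
  DT = {
    m <- rbind(c(-1.4683, -5.1109, -1.4752),
    c(-1.9882, -5.6161, -2.7738),
    c(-1.3600, -6.2202, -0.3359),
    c(-2.3028, -3.9431, -0.7733),
    c(-2.5066, -2.7595, -1.5339),
    c(-3.0268, -1.6469, -0.6174),
    c(-1.9881, -1.2932, 0.3231),
    c(-3.3504, -0.3716, -1.3919),
    c(-4.2860, 0.4393, -0.6802),
    c(-2.0244, 0.3478, -1.4071),
    c(-1.4609, -0.0000, -0.0324),
    c(0.0000, 0.0000, 0.0000),
    c(0.6273, 1.2383, 0.0000),
    c(0.0334, 2.3141, 0.0000),
    c(1.9957, 1.2115, 0.0000),
    c(2.7817, 0.0968, 0.0000),
    c(4.0059, 0.1630, 0.0000),
    c(2.0652, -1.1983, 0.0000),
    c(2.8865, -2.4447, 0.0000),
    c(0.7268, -1.1762, 0.0000))
    rownames(m) <- c("P", "OP1", "OP2", "O5'", "C5'", "C4'", "O4'", "C3'", "O3'", "C2'", "C1'", "N1", "C2", "O2", "N3", "C4", "O4", "C5", "C7", "C6")
    colnames(m) <- c("x","y","z")
    m
  }
)
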