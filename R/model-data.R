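# Empirical amino-acid replacement model constants.
#
# Exchangeability coefficients (lower triangle, column-major, for the amino
# acid order ARNDCQEGHILKMFPSTWYV) and stationary frequencies of three
# standard published models:
#   JTT — Jones, Taylor & Thornton (1992), CABIOS 8:275-282
#   WAG — Whelan & Goldman (2001), Mol Biol Evol 18:691-699
#   LG  — Le & Gascuel (2008), Mol Biol Evol 25:1307-1320
# The absolute scale of the exchangeabilities is irrelevant: rate matrices
# built from them are renormalised to one expected substitution per unit
# branch length at stationarity.

.AA_ALPHABET <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                  "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

.LIGAND_TYPES <- c("DNA", "RNA", "small_molecule", "ion", "peptide")

.jtt_rates <- c(
  58, 54, 81, 56, 57, 105, 179, 27, 36, 30, 35, 54, 15, 194, 378, 475, 9,
  11, 298, 45, 16, 113, 310, 29, 137, 328, 22, 38, 646, 44, 5, 74, 101, 64,
  126, 20, 17, 528, 34, 86, 58, 81, 391, 47, 12, 263, 30, 10, 15, 503, 232,
  8, 70, 16, 10, 49, 767, 130, 112, 11, 7, 26, 15, 4, 15, 59, 38, 4, 46, 31,
  9, 5, 59, 69, 17, 23, 7, 31, 78, 14, 223, 42, 115, 209, 62, 323, 26, 597,
  9, 72, 292, 43, 4, 164, 53, 51, 18, 24, 20, 119, 26, 12, 9, 181, 18, 5,
  18, 30, 32, 10, 7, 45, 23, 6, 6, 27, 14, 5, 24, 201, 33, 55, 8, 47, 16,
  56, 45, 33, 40, 115, 73, 46, 8, 573, 11, 229, 21, 479, 89, 10, 40, 245, 9,
  32, 961, 14, 388, 248, 102, 59, 25, 52, 24, 180, 65, 4, 21, 47, 103, 10,
  8, 14, 43, 16, 29, 226, 24, 18, 323, 17, 92, 12, 53, 536, 62, 285, 118, 6,
  10, 23, 477, 35, 63, 38, 12, 21, 112, 71, 25, 16)

.jtt_freqs <- c(
  0.07674792325, 0.05169094831, 0.04264495736, 0.05154394846, 0.01980298020,
  0.04075195925, 0.06182993817, 0.07315192685, 0.02294397706, 0.05376094624,
  0.09190390810, 0.05867594132, 0.02382597617, 0.04012595987, 0.05090094910,
  0.06876493124, 0.05856494144, 0.01426098574, 0.03210196790, 0.06600493400)

.wag_rates <- c(
  0.5515710, 0.5098480, 0.7389980, 1.0270400, 0.9085980, 1.5828500,
  1.4167200, 0.3169540, 0.1933350, 0.3979150, 0.9062650, 0.8934960,
  0.2104940, 1.4385500, 3.3707900, 2.1211100, 0.1131330, 0.2407350,
  2.0060100, 0.6353460, 0.1473040, 0.5281910, 3.0355000, 0.4391570,
  0.5846650, 2.1371500, 0.1869790, 0.4976710, 5.3514200, 0.6831620,
  0.1027110, 0.6794890, 1.2241900, 0.5544130, 1.1639200, 0.3815330,
  0.2518490, 5.4294200, 0.2652560, 1.5436400, 0.9471980, 1.1255600,
  3.9562900, 0.5542360, 0.1315280, 3.0120100, 0.1982210, 0.0961621,
  0.1950810, 3.9742300, 2.0300600, 0.0719167, 1.0860000, 0.1962460,
  0.0302949, 0.6167830, 6.1741600, 0.8655840, 0.9306760, 0.0394370,
  0.0848047, 0.4798550, 0.1037540, 0.0467304, 0.4239840, 1.0717600,
  0.3748660, 0.1297670, 0.3257110, 0.1523350, 0.0988179, 0.0213520,
  0.3066740, 0.2489720, 0.1701350, 0.3842870, 0.0740339, 0.3904820,
  0.3980200, 0.1094040, 1.4076600, 0.5129840, 0.7170700, 0.5438330,
  1.0021400, 5.4694700, 0.3300520, 4.2941100, 0.1139170, 0.8694890,
  3.8949000, 1.5452600, 0.0999208, 0.9333720, 1.0288700, 0.8579280,
  0.2157370, 0.2277100, 0.3012810, 0.5677170, 0.5700250, 0.1273950,
  0.1542630, 2.5844300, 0.3151240, 0.0811339, 0.6823550, 0.7049390,
  0.8227650, 0.1565570, 0.1963030, 0.5887310, 0.2494100, 0.0304501,
  0.0613037, 0.3735580, 0.1741000, 0.0499310, 0.2435700, 1.3418200,
  0.2258330, 0.3369830, 0.1036040, 0.1872470, 0.1381900, 0.4994620,
  0.8904320, 0.4041410, 0.6793710, 0.6961980, 0.7401690, 0.4733070,
  0.2625690, 3.8734400, 0.1183580, 3.1709700, 0.3238320, 4.2574600,
  1.0594700, 0.0999288, 0.3194400, 1.4581600, 0.2124830, 0.4201700,
  7.8213000, 0.2575550, 4.8540200, 2.1151700, 0.4158440, 0.3447390,
  0.3266220, 0.6653090, 0.3986180, 1.8003400, 0.9342760, 0.0888360,
  0.5568960, 0.9671300, 1.3869800, 0.1375050, 0.1332640, 0.3054340,
  1.1906300, 0.1713290, 0.4939050, 1.5161200, 0.5157060, 0.4284370,
  2.0584500, 0.1614440, 0.5459310, 0.1719030, 1.5296400, 6.4542800,
  0.6498920, 1.6132800, 0.7953840, 0.1394050, 0.2160460, 0.3148870,
  4.3780200, 0.5237420, 0.7869930, 0.2327390, 0.1108640, 0.2911480,
  1.3882300, 2.4853900, 0.3653690, 0.3147300)

.wag_freqs <- c(
  0.08662790866, 0.04397200440, 0.03908940391, 0.05704510570, 0.01930780193,
  0.03672810367, 0.05805890581, 0.08325180833, 0.02443130244, 0.04846600485,
  0.08620900862, 0.06202860620, 0.01950270195, 0.03843190384, 0.04576310458,
  0.06951790695, 0.06101270610, 0.01438590144, 0.03527420353, 0.07089560709)

.lg_rates <- c(
  0.425093, 0.276818, 0.395144, 2.489084, 0.969894, 1.038545, 2.066040,
  0.358858, 0.149830, 0.395337, 0.536518, 1.124035, 0.253701, 1.177651,
  4.727182, 2.139501, 0.180717, 0.218959, 2.547870, 0.751878, 0.123954,
  0.534551, 2.807908, 0.363970, 0.390192, 2.426601, 0.126991, 0.301848,
  6.326067, 0.484133, 0.052722, 0.332533, 0.858151, 0.578987, 0.593607,
  0.314440, 0.170887, 5.076149, 0.528768, 1.695752, 0.541712, 1.437645,
  4.509238, 0.191503, 0.068427, 2.145078, 0.371004, 0.089525, 0.161787,
  4.008358, 2.000679, 0.045376, 0.612025, 0.083688, 0.062556, 0.523386,
  5.243870, 0.844926, 0.927114, 0.010690, 0.015076, 0.282959, 0.025548,
  0.017416, 0.394456, 1.240275, 0.425860, 0.029890, 0.135107, 0.037967,
  0.084808, 0.003499, 0.569265, 0.640543, 0.320627, 0.594007, 0.013266,
  0.893680, 1.105251, 0.075382, 2.784478, 1.143480, 0.670128, 1.165532,
  1.959291, 4.128591, 0.267959, 4.813505, 0.072854, 0.582457, 3.234294,
  1.672569, 0.035855, 0.624294, 1.223828, 1.080136, 0.236199, 0.257336,
  0.210332, 0.348847, 0.423881, 0.044265, 0.069673, 1.807177, 0.173735,
  0.018811, 0.419409, 0.611973, 0.604545, 0.077852, 0.120037, 0.245034,
  0.311484, 0.008705, 0.044261, 0.296636, 0.139538, 0.089586, 0.196961,
  1.739990, 0.129836, 0.268491, 0.054679, 0.076701, 0.108882, 0.366317,
  0.697264, 0.442472, 0.682139, 0.508851, 0.990012, 0.584262, 0.597054,
  5.306834, 0.119013, 4.145067, 0.159069, 4.273607, 1.112727, 0.078281,
  0.064105, 1.033739, 0.111660, 0.232523, 10.649107, 0.137500, 6.312358,
  2.592692, 0.249060, 0.182287, 0.302936, 0.619632, 0.299648, 1.702745,
  0.656604, 0.023918, 0.390322, 0.748683, 1.136863, 0.049906, 0.131932,
  0.185202, 1.798853, 0.099849, 0.346960, 2.020366, 0.696175, 0.481306,
  1.898718, 0.094464, 0.361819, 0.165001, 2.457121, 7.803902, 0.654683,
  1.338132, 0.571468, 0.095131, 0.089613, 0.296501, 6.472279, 0.248862,
  0.400547, 0.098369, 0.140825, 0.245841, 2.188158, 3.151815, 0.189510,
  0.249313)

.lg_freqs <- c(
  0.07906592093, 0.05594094406, 0.04197695802, 0.05305194695, 0.01293698706,
  0.04076695923, 0.07158592841, 0.05733694266, 0.02235497765, 0.06215693784,
  0.09908090092, 0.06459993540, 0.02295097705, 0.04230195770, 0.04403995596,
  0.06119693880, 0.05328694671, 0.01206598793, 0.03415496585, 0.06914693085)

.model_registry <- list(
  JTT = list(rates = .jtt_rates, freqs = .jtt_freqs),
  WAG = list(rates = .wag_rates, freqs = .wag_freqs),
  LG  = list(rates = .lg_rates,  freqs = .lg_freqs))
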