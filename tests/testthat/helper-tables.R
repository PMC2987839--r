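# Published-table fixtures, transcribed as code. These printed summaries are
# the package's real-data inputs: per-locus absolute mutation rates with 95%
# confidence limits and relative rates (the rates table), the two lacZ
# mutant-class distributions (in vitro spectra), and the four CAN1 forward
# mutation spectra.

# Rates table: one row per strain, columns per locus:
# <locus>_rate, <locus>_lo, <locus>_hi, <locus>_rel  (rates in 1e-8 units).
rates_table1 <- local({
  txt <- "strain|his_rate|his_lo|his_hi|his_rel|lys_rate|lys_lo|lys_hi|lys_rel|can_rate|can_lo|can_hi|can_rel
wt|1.5|0.6|2.4|1|12.9|9.5|26.2|1|10.1|3.9|14.6|1
dpb3|4.4|3.6|5.7|3.9|35.7|31.9|56.7|2.8|81.8|72.2|95.2|8.1
dpb4|3.7|3.0|5.0|2.5|22.3|19.9|28.6|1.7|63.4|57.3|71.4|6.3
dpb3 dpb4|4.1|2.5|5.1|2.7|33.4|25.9|46.4|2.6|74.3|66.4|89.5|7.4
pol2-4|6.9|4.2|8.6|4.6|35.7|32.9|48.3|2.7|77.9|69.4|90.5|7.7
pol2-4 dpb3|13.4|10.9|18.8|8.9|44.5|37.8|52.5|3.4|153|128|210|15.1
pol2-4 dpb4|28.1|23.0|30.4|18.7|44.5|39.1|59.9|3.4|224|200|268|22.2
pol2-4 dpb3 dpb4|22.1|18.5|26.8|14.8|41.0|35.6|49.3|3.2|132|123|170|13
msh6|5.3|3.5|6.7|3.5|2720|2390|3690|211|165|119|226|16.3
msh6 dpb3|7.0|5.5|9.4|4.6|1360|1100|1550|105|299|216|399|29.6
msh6 dpb4|7.6|6.3|9.3|5.1|1430|1180|1590|111|278|217|344|27.5
msh6 dpb3 dpb4|9.0|8.1|12.4|6.0|2200|2060|2830|171|261|217|346|25.8
msh6 pol2-4|71.1|55.7|82.7|47.4|7180|6190|8870|557|7150|6410|9810|708
msh6 pol2-4 dpb3|72.6|45.9|119|48.4|2460|1800|4670|190|13400|11200|17000|1320
msh6 pol2-4 dpb4|76.6|32.6|121|51.1|2590|1870|5510|201|17800|10500|21100|1760
msh6 pol2-4 dpb3 dpb4|68.6|54.9|100|45.7|2600|594|4010|201|8450|6670|13800|837
pol3-5DV|7.3|6.2|8.8|4.9|71|57|77|5.5|350|304|419|35
pol3-5DV dpb3 dpb4|17.8|15|21|11.9|67|54|85|5.2|363|288|547|36"
  utils::read.delim(text = txt, sep = "|", stringsAsFactors = FALSE)
})

# rev3 suppression row (separate table; reference strain is dpb3 dpb4):
# Can-r 26 (20.7-29.1), relative 0.3 versus 74.3.
rev3_can <- list(rate = 26, lo = 20.7, hi = 29.1, rel = 0.3, ref = 74.3)

# In vitro lacZ mutant-class counts for the exonuclease-deficient
# holoenzyme (pol2-4, four subunits) and the pol2-4/Dpb2 two-subunit
# complex; mutant frequencies 0.026 and 0.029, N sequenced 285 and 277.
lacz_classes <- c("substitutions", "-1 frameshifts", "+1 frameshifts",
                  "other")
spectrum_holo <- function()
  mutation_spectrum(c(214, 53, 9, 11), categories = lacz_classes,
                    label = "holoenzyme pol2-4")
spectrum_2sub <- function()
  mutation_spectrum(c(229, 35, 7, 29), categories = lacz_classes,
                    label = "pol2-4/Dpb2")

# CAN1 forward mutation spectra: 10 classes x 4 strains
can1_classes <- c("AT->TA", "AT->CG", "AT->GC", "GC->CG", "GC->AT",
                  "GC->TA", "-1 frameshifts", "+1 frameshifts", "Complex",
                  "Other")
can1_counts <- data.frame(
  category     = can1_classes,
  wt           = c(1, 2, 3, 12, 7, 10, 5, 2, 1, 5),
  `dpb3 dpb4`  = c(1, 1, 3, 9, 9, 8, 9, 1, 5, 3),
  `pol2-4`     = c(6, 5, 5, 4, 3, 6, 5, 11, 2, 1),
  `pol2-4 dpb3 dpb4` = c(6, 4, 0, 8, 2, 7, 9, 6, 3, 3),
  check.names = FALSE)
can1_spectrum <- function(strain)
  mutation_spectrum(can1_counts[[strain]], categories = can1_classes,
                    label = strain)
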