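#!/usr/bin/env Rscript
# Regenerates the frozen cross-implementation oracle values used by
# tests/testthat/test-feature-oracle.R. Runs the independently coded Python
# oracle (radiomic_oracle.py; numpy/scipy/scikit-image/trimesh) on the five
# deterministic phantom cases defined in tests/testthat/helper-fixtures.R and
# writes tests/testthat/oracle-feature-values.csv.
#
# Run from the package root: Rscript tools/oracle/freeze_oracle.R

library(radrepro)
source("tests/testthat/helper-fixtures.R")

tmp <- tempfile("oracle")
dir.create(tmp)
rows <- list()
for (i in 1:5) {
  cs <- oracle_phantom_case(i)
  img_f <- file.path(tmp, sprintf("img%d.csv", i))
  msk_f <- file.path(tmp, sprintf("msk%d.csv", i))
  write(format(as.vector(cs$image$data), digits = 17), img_f, ncolumns = 1)
  write(as.vector(cs$mask$data), msk_f, ncolumns = 1)
  d <- dim(cs$image$data)
  sp <- cs$image$spacing
  out <- system2("python",
                 c("tools/oracle/radiomic_oracle.py", img_f, msk_f,
                   d[1], d[2], d[3], sp[1], sp[2], sp[3], 25),
                 stdout = TRUE)
  vals <- read.csv(text = out, header = FALSE,
                   col.names = c("name", "value"))
  vals$case <- i
  rows[[i]] <- vals
  message("case ", i, ": ", nrow(vals), " oracle features")
}
all <- do.call(rbind, rows)[, c("case", "name", "value")]
write.csv(all, "tests/testthat/oracle-feature-values.csv", row.names = FALSE)
message("froze ", nrow(all), " values")
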