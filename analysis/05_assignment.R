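#!/usr/bin/env Rscript
# Stage 5: similarity-based identification.
#
# Leave-one-out evaluation of the >= 95 %-identity + conspecific-dominance
# rule for every locus and combination, followed by the regional design:
# the largest plot's specimens form the reference database and the other
# plots' specimens (restricted to taxa shared with the database) are the
# queries. Also tabulates shared species/genus counts per plot pair.
# Writes results/tables/assignment_*.tsv and shared_taxa.tsv.

library(barcodeval)

ds <- read_dataset("results/data")
dir.create("results/tables", showWarnings = FALSE, recursive = TRUE)

combos <- list("rbcL", "matK", "trnH-psbA", "ITS",
               c("rbcL", "matK"),
               c("rbcL", "matK", "trnH-psbA"),
               c("rbcL", "matK", "ITS"),
               c("rbcL", "matK", "trnH-psbA", "ITS"))

loo <- do.call(rbind, c(lapply(combos, function(combo) {
  evaluate_leave_one_out(ds, combo)$report
}), list(make.row.names = FALSE)))
write.table(loo, "results/tables/assignment_leave_one_out.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
print(loo[, c("label", "rank", "n_queries", "correct", "incorrect",
              "no_assignment", "rate")])

# regional evaluation: biggest plot as the database
plot_sizes <- table(ds$specimens$plot)
db_plot <- names(sort(plot_sizes, decreasing = TRUE))[1]
cp <- evaluate_cross_plot(ds, db_plot = db_plot,
                          loci = c("rbcL", "matK", "trnH-psbA", "ITS"))
write.table(cp$report, "results/tables/assignment_cross_plot.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat(sprintf("\nCross-plot evaluation, database = %s:\n", db_plot))
print(cp$report[, c("query_plot", "rank", "n_queries", "correct", "rate",
                    "n_shared")])

shared <- shared_taxa_counts(ds)
write.table(shared, "results/tables/shared_taxa.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
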