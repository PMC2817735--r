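# Lazily computed, cached study runs shared by the acceptance-level tests.
# Replication is desk-scale: N = 100 datasets per sub-simulation for
# support-interval summaries, N = 50 (at D = 0) / 25 (elsewhere) with
# B = 200 bootstraps and P = 100 permutations for the bootstrap methods.
# Tolerances on reference benchmark cell means are +/- 3 standard errors inflated by
# sqrt(N_full / N_reduced), plus a 20% engine allowance (regression CIM in
# place of ECM likelihood; see the methods vignette).

.acc_cache <- new.env(parent = emptyenv())

acc_si_study <- function() {
    if (is.null(.acc_cache$si))
        .acc_cache$si <- runFullStudy(studyConfig(N = 100, seed = 20260922),
                                      methods = "si")
    .acc_cache$si
}

acc_boot_study <- function() {
    if (is.null(.acc_cache$boot)) {
        cfg50 <- studyConfig(N = 50, B = 200, P = 100, seed = 20260923)
        sub0 <- runSubsimulation(0, cfg50,
                                 methods = c("si", "npci", "cim-npci"))
        cfg25 <- studyConfig(N = 25, B = 200, P = 100, seed = 20260924)
        subs <- lapply(c(0.10, 0.30, 0.50), runSubsimulation, config = cfg25,
                       methods = c("npci", "cim-npci"))
        .acc_cache$boot <- list(sub0 = sub0, subs = subs)
    }
    .acc_cache$boot
}

# 16-cell mean-width table (selective variant) for one bootstrap method.
acc_boot_cells <- function(method) {
    b <- acc_boot_study()
    summ <- rbind(b$sub0$summary, do.call(rbind, lapply(b$subs, `[[`, "summary")))
    s <- summ[summ$method == method & summ$selective %in% TRUE, ]
    s[order(s$D, s$chrom), ]
}

# Reference benchmark cell values (rows D = 0, 10, 30, 50%; columns Q1..Q4).
refWidths <- list(
    SI = list(width = c(4.8, 4.4, 9.3, 11.5, 5.0, 4.9, 11.6, 14.5,
                        6.1, 6.0, 13.9, 17.3, 6.0, 6.2, 14.7, 17.8),
              se = c(.19, .06, .08, .10, .10, .07, .12, .12,
                     .20, .08, .12, .22, .11, .08, .21, .17)),
    NPCI = list(width = c(4.5, 4.1, 5.4, 6.3, 7.4, 7.8, 11.7, 14.4,
                          7.6, 8.2, 16.5, 21.5, 7.4, 8.4, 18.3, 22.3),
                se = c(.27, .26, .27, .33, .38, .39, .54, .60,
                       .37, .39, .72, .92, .38, .39, .73, .90)),
    `CIM-NPCI` = list(width = c(7.5, 7.5, 8.9, 11.1, 7.1, 7.5, 10.7, 13.2,
                                7.5, 8.4, 16.1, 20.0, 7.4, 8.6, 18.1, 21.6),
                      se = c(.13, .13, .14, .17, .11, .12, .16, .17,
                             .13, .12, .21, .27, .11, .12, .22, .28)))

# +/- 3 inflated SEs plus the 20% engine allowance.
acc_tol <- function(value, se, inflate) 3 * se * inflate + 0.20 * value
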