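# Study-scale fixtures for the acceptance checks: a full synthetic
# substrate study (63 positives, 14 known negatives, 631 unlabeled,
# full-strength signature), its CPP features, dPULearn balancing, and the
# complete 25-round, 10-model training run. Built once and shared.

study_run <- function() {
  fixture("study_run", function() {
    sim <- synth_dataset(n_pos = 63, n_neg = 14, n_unlabeled = 631,
                         effect = 1, seed = 101)
    scales <- synth_scaleset(25, 8, seed = 101)
    res <- cpp_run(sim$data, scales, n_filter = 100,
                   ref_labels = "unlabeled")
    pu <- dpulearn(res$matrix, res$labels, n_needed = "auto")
    labels2 <- res$labels
    labels2[pu$selected_ids] <- "negative"
    t_start <- Sys.time()
    bundle <- monte_carlo_train(res$matrix, labels2, n_rounds = 25,
                                seed_base = 101)
    train_minutes <- as.numeric(difftime(Sys.time(), t_start,
                                         units = "mins"))
    list(sim = sim, scales = scales, res = res, pu = pu, labels2 = labels2,
         bundle = bundle, train_minutes = train_minutes)
  })
}
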