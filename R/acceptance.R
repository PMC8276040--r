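#' Scaled-down classification benchmark
#'
#' The package's reference benchmark run: generate the default
#' well-separated synthetic phenotype dataset (400 cells per class,
#' data seed 42), split 70/15/15 stratified, train the reduced-width
#' network (input 64, width factor 1/8, at most 30 epochs, Adam learning
#' rate 0.001, batch 64, dropout 0.5) with dihedral augmentation on the
#' training partition only, and evaluate accuracy on the untouched test
#' partition.
#'
#' @param seed integer seed driving the split, weight initialization,
#'   shuffling and dropout.
#' @param n_per_class cells per phenotype (400 for the reference run;
#'   smaller values give a faster, less stable estimate).
#' @param data_seed seed of the dataset generator (fixed at 42 for the
#'   reference run).
#' @param epochs maximum training epochs.
#' @return list: `accuracy`, `confusion`, `per_class_recall`, `history`,
#'   `n_test`.
#' @export
acceptance_t6 <- function(seed = 1L, n_per_class = 400L, data_seed = 42L,
                          epochs = 30L) {
  ds <- generate_dataset(n_per_class, 64L, seed = data_seed)
  sp <- split_dataset(ds$labels, c(0.70, 0.15, 0.15), seed = seed)
  cfg <- train_config(learning_rate = 0.001, batch_size = 64L,
                      dropout = 0.5, epochs = epochs, seed = seed,
                      augment = TRUE, early_stop_val_acc = 0.99)
  model <- build_model(model_spec("reduced"), seed = seed)
  fit <- train_cnn(model, ds$images[, , sp$train], ds$labels[sp$train],
                   ds$images[, , sp$val], ds$labels[sp$val], cfg)
  ev <- evaluate_cnn(fit$model, ds$images[, , sp$test],
                     ds$labels[sp$test])
  list(accuracy = ev$accuracy, confusion = ev$confusion,
       per_class_recall = ev$per_class_recall, history = fit$history,
       n_test = length(sp$test))
}
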