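#' End-to-end pipeline configuration
#'
#' Bundles the per-stage configurations for a complete run: generate a
#' synthetic web, train the relevance classifier, crawl, evaluate the crawl
#' and analyze the host graph. All randomness flows from `seed` through
#' named per-stage substreams.
#'
#' @param seed Master seed.
#' @param corpus A [corpus_config()] (its `rng_seed` is re-derived from
#'   `seed`).
#' @param web A [web_config()] (likewise re-seeded).
#' @param crawl A [crawl_config()].
#' @param svm_grid Hyperparameter grid for [train_grid_cv()].
#' @param cv_folds,n_features Training settings.
#' @param train_fraction Train share of the balanced corpus split.
#' @param target_count Targets withheld for the seed-target recall estimate.
#' @param hr_interval Fetches per harvest-rate interval.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L,
                            corpus = corpus_config(n_docs_per_class = 1200),
                            web = web_config(n_hosts = 200),
                            crawl = crawl_config(max_pages = 400L),
                            svm_grid = small_svm_grid(),
                            cv_folds = 5L,
                            n_features = 200L,
                            train_fraction = 0.8,
                            target_count = 30L,
                            hr_interval = 50L) {
  corpus$rng_seed <- as.integer(substream_seed(seed, "corpus"))
  web$rng_seed <- as.integer(substream_seed(seed, "web"))
  structure(
    list(seed = as.integer(seed), corpus = corpus, web = web, crawl = crawl,
         svm_grid = svm_grid, cv_folds = as.integer(cv_folds),
         n_features = as.integer(n_features),
         train_fraction = train_fraction,
         target_count = as.integer(target_count),
         hr_interval = as.integer(hr_interval)),
    class = "pipeline_config"
  )
}

#' Run the full synthetic-web study pipeline
#'
#' Stages: synthetic web generation, classifier training (information gain,
#' tfc weighting, cross-validated RBF-SVM grid search), seed-target split,
#' focused crawl over the in-memory transport, crawl evaluation (harvest
#' rate, recall estimate) and host-graph metrics. Writes each stage's
#' artifacts plus a single `summary.json` and the resolved configuration
#' into `out_dir` when given. Deterministic for a fixed configuration.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory, or `NULL` to skip writing artifacts.
#' @param quiet Suppress per-stage progress messages.
#' @return A list of class `pipeline_result`: the per-stage objects plus
#'   `summary` (a flat named list of the headline numbers).
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL,
                         quiet = FALSE) {
  say <- function(...) if (!quiet) message("[focuscrawl] ", ...)
  if (!is.null(out_dir)) dir.create(out_dir, showWarnings = FALSE,
                                    recursive = TRUE)

  say("stage synth-web: generating corpus and web")
  corpus <- generate_corpus(config$corpus)
  web <- generate_web(config$web, corpus)

  say("stage train-classifier: ", nrow(corpus), " documents")
  # train on documents not embedded in the web, so crawled pages are unseen
  unused <- corpus[!(corpus$id %in% web$pages$doc_id), ]
  train_corpus <- if (sum(unused$class == "H") >= 25 &&
                      sum(unused$class == "G") >= 25) unused else corpus
  split <- split_and_balance(train_corpus, config$train_fraction,
                             seed = substream_seed(config$seed, "split"))
  model <- train_grid_cv(split$train, grid = config$svm_grid,
                         folds = config$cv_folds,
                         seed = substream_seed(config$seed, "svm"),
                         k = config$n_features)
  test_eval <- evaluate_model(model, split$test)

  say("stage crawl: budget ", config$crawl$max_pages, " pages")
  all_seeds <- web_seed_urls(web)
  sp <- stratified_split(all_seeds, config$target_count,
                         seed = substream_seed(config$seed, "targets"))
  transport <- synthetic_transport(web)
  result <- crawl(sp$seeds$url, model, config$crawl, transport)

  say("stage eval-crawl")
  hs <- harvest_rate(result, interval = config$hr_interval)
  fetched_urls <- result$records$url[result$records$status == "ok"]
  recall_est <- estimate_recall(fetched_urls, sp$targets$url)

  say("stage graph-metrics")
  hg <- aggregate_hosts(result$edges)
  gm <- graph_metrics(hg, seed = substream_seed(config$seed, "louvain"))
  ranking <- rank_and_tally(gm$pagerank)

  summary <- list(
    n_documents = nrow(corpus),
    n_hosts = nrow(web$hosts),
    n_pages = nrow(web$pages),
    classifier_cv_accuracy = model$best$cv_accuracy,
    classifier_accuracy = test_eval$accuracy,
    classifier_precision = test_eval$precision,
    classifier_recall = test_eval$recall,
    n_fetched = sum(result$records$status == "ok"),
    n_indexed = sum(result$records$indexed),
    mean_harvest_rate = mean_harvest_rate(hs),
    final_harvest_rate = mean_harvest_rate(hs, "final"),
    recall_estimate = recall_est,
    graph_nodes = gm$degree$n_nodes,
    graph_edges = gm$degree$n_edges,
    graph_avg_degree = gm$degree$avg_degree,
    graph_diameter = gm$diameter,
    graph_avg_path_length = gm$avg_path_length,
    graph_modularity = gm$modularity
  )

  if (!is.null(out_dir)) {
    write_corpus_jsonl(corpus, file.path(out_dir, "corpus.jsonl"))
    write_web(web, file.path(out_dir, "web"))
    write_crawl_records(result, file.path(out_dir, "crawl_records.jsonl"))
    write_edges_tsv(result$edges, file.path(out_dir, "crawl_edges.tsv"))
    utils::write.csv(as.data.frame(hs), file.path(out_dir, "harvest.csv"),
                     row.names = FALSE)
    write_host_graph(hg, file.path(out_dir, "host_graph.graphml"))
    utils::write.csv(ranking$tables, file.path(out_dir, "topk_hosts.csv"),
                     row.names = FALSE)
    jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA)
    jsonlite::write_json(resolved_config(config),
                         file.path(out_dir, "config.json"),
                         auto_unbox = TRUE, digits = NA)
  }

  structure(
    list(corpus = corpus, web = web, model = model, test_eval = test_eval,
         split = sp, crawl = result, harvest = hs,
         recall_estimate = recall_est, host_graph = hg, metrics = gm,
         ranking = ranking, summary = summary, config = config),
    class = "pipeline_result"
  )
}

resolved_config <- function(config) {
  strip <- function(x) {
    if (is.list(x)) {
      lapply(unclass(x), strip)
    } else if (is.function(x)) {
      "<function>"
    } else {
      x
    }
  }
  strip(config)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>\n")
  s <- x$summary
  cat(sprintf("  classifier accuracy %.3f | mean HR %.3f | recall %.3f\n",
              s$classifier_accuracy, s$mean_harvest_rate, s$recall_estimate))
  cat(sprintf("  graph: %d nodes, %d edges, Q = %.3f\n",
              s$graph_nodes, s$graph_edges, s$graph_modularity))
  invisible(x)
}

#' One-row summary of a pipeline run
#' @param x A `pipeline_result`.
#' @param ... Unused.
#' @return Tibble with the headline metrics of the run.
#' @export
glance.pipeline_result <- function(x, ...) {
  tibble::as_tibble(x$summary)
}
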