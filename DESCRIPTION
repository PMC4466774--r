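Package: gsrank
Title: Ranking-Based Genomic Selection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Genomic selection treated as a learning-to-rank problem rather
    than a regression problem. Provides top-k ranking evaluation measures
    (DCG, NDCG, Mean NDCG, pairwise accuracy, Kendall's tau on strict
    preference pairs), ranking learners (kernel RankSVM with squared hinge
    loss, multiclass and ordinal McRank, LambdaMART) alongside regression
    baselines (kernel ridge / RKHS regression, gradient-boosted regression
    trees, random forests), a randomized 80/20 cross-validation benchmarking
    protocol with nested measure-targeted hyper-parameter tuning, and a
    synthetic genotype/phenotype simulator for the n << p marker regime.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ranger,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
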