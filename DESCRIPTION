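Package: raackit
Title: Reduced Amino Acid Alphabet Features and Protein Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for working with reduced amino acid alphabets (RAACs):
    loading and validating alphabet reduction schemes, rewriting protein
    sequences over cluster representatives, extracting normalized K-tuple
    reduced amino acid composition features under three correlation
    parameters (K-tuple size, g-gap between windows, lambda spacing within
    windows), computing sequence-logo and alignment visualization tables,
    and training and evaluating binary protein classifiers (SVM, KNN,
    random forest) with stratified k-fold or leave-one-out cross-validation
    reported as pooled Sn/Sp/Acc/MCC and ROC/AUC.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    class,
    e1071,
    jsonlite,
    randomForest,
    stats,
    tools,
    utils
Suggests:
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
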