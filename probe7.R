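library(seosdd)
set.seed(13)
v <- c(sample(30:55, 2500, TRUE), sample(170:220, 5692, TRUE))
img <- grayImage(matrix(as.integer(v[1:(90*90)]), 90, 90))
pr <- selectRange(findCandidates(slopeDifference(intensityHistogram(img))), "auto")
cat("cand:", candidates(pr), "\n")
tr <- binarySearchThreshold(img, pr, polarity="dark", exhaustive=TRUE)
print(searchTrace(tr)); cat("sel:", selectedThreshold(tr), "\n")
inv <- grayImage(255L - pixels(img))
prI <- selectRange(findCandidates(slopeDifference(intensityHistogram(inv))), "auto")
cat("candI:", candidates(prI), " mirror:", 255 - rev(candidates(prI)), "\n")
trI <- binarySearchThreshold(inv, prI, polarity="bright", exhaustive=TRUE)
print(searchTrace(trI)); cat("selI:", selectedThreshold(trI), " mirror:", 255 - selectedThreshold(trI), "\n")
m1 <- binarize(img, selectedThreshold(tr), "dark")
m2 <- binarize(inv, selectedThreshold(trI), "bright")
cat("mask agreement:", mean(m1 == m2), "\n")
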