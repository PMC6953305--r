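# SYNTHETIC placeholder five-level grading table (NY/T 593-2002 style).
# Scores 10/8/6/4/2 per level so nine level-1 traits total the full 90.
# Cut points are plausible values for indica rice, not a transcription of
# any published standard; replace with real thresholds before use.
BRR:
  direction: higher_better
  cuts: [81.0, 79.0, 77.0, 75.0]
  scores: [10, 8, 6, 4, 2]
  range: [0.0, 100.0]
MRR:
  direction: higher_better
  cuts: [72.0, 70.0, 68.0, 66.0]
  scores: [10, 8, 6, 4, 2]
  range: [0.0, 100.0]
HRR:
  direction: higher_better
  cuts: [66.0, 61.0, 56.0, 51.0]
  scores: [10, 8, 6, 4, 2]
  range: [0.0, 100.0]
PCG:
  direction: lower_better
  cuts: [10.0, 20.0, 30.0, 40.0]
  scores: [10, 8, 6, 4, 2]
  range: [0.0, 100.0]
CAS:
  direction: lower_better
  cuts: [10.0, 20.0, 30.0, 40.0]
  scores: [10, 8, 6, 4, 2]
  range: [0.0, 100.0]
CD:
  direction: lower_better
  cuts: [1.0, 3.0, 5.0, 8.0]
  scores: [10, 8, 6, 4, 2]
  range: [0.0, 100.0]
GT:
  direction: higher_better
  cuts: [6.0, 5.0, 4.0, 3.0]
  scores: [10, 8, 6, 4, 2]
  range: [1.0, 7.0]
GC:
  direction: higher_better
  cuts: [70.0, 60.0, 50.0, 40.0]
  scores: [10, 8, 6, 4, 2]
  range: [0.0, 200.0]
AC:
  direction: lower_better
  cuts: [15.0, 17.0, 19.0, 21.0]
  scores: [10, 8, 6, 4, 2]
  range: [0.0, 100.0]
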