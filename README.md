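# needsim

Exposure assessment needs to know where and how people spend their time:
contact with consumer products, indoor air, and other stressors is driven by
the daily pattern of sleeping, eating, commuting, and working. Longitudinal
activity-diary surveys that would capture those patterns over more than a
day are scarce and expensive. `needsim` generates such diaries
synthetically: it simulates a working adult as an agent-based model driven
by **needs-based artificial intelligence**, producing week-scale,
minute-resolution activity diaries with realistic day-to-day variation. It
is intended for exposure modelers and time-use researchers who need
longitudinal behavior traces as input to downstream assessments.

## The model

The agent carries four needs — *Rest*, *Hunger*, *Income*, *Travel* — each
with a **satiation** n(t) ∈ [0, 1] (0 = fully unsatisfied) and a threshold
λ. The agent only seeks to address a need once n(t) ≤ λ.

Satiation declines in one of two ways:

* **Linear needs** (Rest, Hunger) decay at a constant rate
  m_decay = −(1 − λ)/Δt_decay, where Δt_decay is the time from full
  satiation to the threshold. While the satisfying activity runs, satiation
  recovers at m_recover = (1 − λ)/Δt_recover, and the realized episode
  length is Δt_activity = (1 − n)/m_recover — an agent that starts late
  (n < λ) sleeps or eats *longer* than the minimum.
* **Step needs** (Income, Travel) model scheduled commitments: satiation is
  1 before a clock trigger t₀ and drops to a small value η (0 ≤ η ≤ λ) at
  t₀; completing the activity restores it to 1.

When a need is unsatisfied, objects sharing the agent's environment (bed
and food in the residence; occupational objects and food in the workplace;
transport outdoors) **advertise** activities. An advertisement promising to
move satiation from n to n + δ is scored with the urgency weight
W(n) = 1/(n + ε) (zero above threshold):

    S(n) = W(n(t)) − W(n(t) + δ),    for n ≤ λ   (else 0)

Each minute the agent performs the highest-scoring positive advertisement,
or stays idle. Work is the only interruptible activity, and only lunch may
interrupt it; commutes are linked to work (the morning commute ends at the
work start, the evening commute starts at the work end). Because Travel's η
is set very low, leaving for work outranks eating breakfast — an agent that
oversleeps past the commute urge skips breakfast, as real commuters do.

Day-to-day variation comes from sampling each activity parameter (start,
end, or duration, per activity) from a normal distribution with mean μ
(long-term average) and standard deviation σ (day-to-day variation),
truncated to μ ± σ.

## Worked example

Simulate the default week-long scenario (7 days plus an 8-hour warm-up
evening, starting Sunday 16:00) with the shipped parameterization:

```r
library(needsim)
diary <- run_simulation(sim_config(), seed = 42)
print(diary, n = 12)
```

```
<activity_diary> 69 entries, 10560 minutes
 Day Start time End time Duration          Activity Weekday Environment
   0      16:00    19:02    03:02              Idle  Sunday   Residence
   0      19:02    19:47    00:45        Eat dinner  Sunday   Residence
   0      19:47    22:23    02:36              Idle  Sunday   Residence
   0      22:23    10:05    11:42             Sleep  Sunday   Residence
   1      10:05    10:35    00:30   Commute to work  Monday    Outdoors
   1      10:35    11:54    01:19              Work  Monday   Workplace
   1      11:54    12:39    00:45         Eat lunch  Monday   Workplace
   1      12:39    17:02    04:23              Work  Monday   Workplace
   1      17:02    18:02    01:00 Commute from work  Monday    Outdoors
   1      18:02    18:53    00:51              Idle  Monday   Residence
   1      18:53    19:39    00:46        Eat dinner  Monday   Residence
   1      19:39    22:11    02:32              Idle  Monday   Residence
... and 57 more entries
```

The trace already shows the model's signature behaviors: on Monday the
agent oversleeps to 10:05, past the 8:30 commute urge, so it *skips
breakfast* and commutes immediately; the workday is correspondingly
shortened (work still ends near its sampled 17:00 end time); and the first
meal of the day runs long (45 min rather than the 30-min lunch minimum)
because Hunger is deeply depleted by then.

```r
s <- summarize_diary(diary)
s[s$activity != "Idle", ]
```

```
          activity episodes days start_mean_h duration_mean_min
             Sleep        8    8       22.150            558.75
     Eat breakfast        5    5        8.977             15.80
   Commute to work        5    5        8.997             30.00
              Work       10    5       11.047            207.10
         Eat lunch        7    7       12.024             34.71
 Commute from work        5    5       17.010             60.00
        Eat dinner        8    8       18.983             46.62
```

Work occurs on exactly 5 distinct days (10 episodes: two blocks around
lunch each workday), commutes only on workdays, meals every day — with
breakfast missing on 2 of the 7 full days (late wakes), eaten on 5.

Diaries round-trip through CSV with `write_diary()` / `read_diary()`, and
`oracle_schedule()` computes the zero-variance weekly schedule analytically
as an independent check of the engine. A thin CLI wraps these functions:

```sh
exec/needsim simulate --seed 3 --out diary.csv
exec/needsim summarize --diary diary.csv
```

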