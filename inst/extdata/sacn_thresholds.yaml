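# Default SACN recommendation thresholds (see ?sacn_thresholds).
# Bounds are inclusive; direction "ge" means intake must be >= bound,
# "le" means <= bound. Units are fixed by the person-totals fields.
fruit_veg:          {bound: 5,  direction: ge}   # portions/day (80 g each)
oily_fish:          {bound: 20, direction: ge}   # g/day (140 g portion/week)
red_processed_meat: {bound: 70, direction: le}   # g/day
nmes:               {bound: 11, direction: le}   # % food energy
fat:                {bound: 35, direction: le}   # % food energy
satfat:             {bound: 11, direction: le}   # % food energy
fibre:              {bound: 18, direction: ge}   # g/day
salt:               {bound: 6,  direction: le}   # g/day
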