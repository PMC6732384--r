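"name","max_ma","min_ma"
"bin01",500,497.5
"bin02",497.5,495
"bin03",495,492.5
"bin04",492.5,490
"bin05",490,487.5
"bin06",487.5,485
"bin07",485,482.5
"bin08",482.5,480
"bin09",480,477.5
"bin10",477.5,475
"bin11",475,472.5
"bin12",472.5,470
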