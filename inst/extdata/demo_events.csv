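subject_id,timestamp_ms,event_type
demo-6,1598400000000,screen_on
demo-6,1598400000100,touch
demo-6,1598400001100,touch
demo-6,1598400001500,touch
demo-6,1598400003100,touch
demo-6,1598400003500,touch
demo-6,1598400005100,touch
demo-6,1598400006100,screen_off
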