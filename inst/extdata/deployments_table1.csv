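test_id,n_videos,n_playback,n_predator,n_noise,n_cancelled,logging_h,failed
LBP00,3,3,2,1,0,21.3,FALSE
LBP01,4,2,2,0,2,7.9,FALSE
LBP02,0,0,0,0,0,1.6,TRUE
LBP03,12,9,5,4,3,14.4,FALSE
LBP04,0,0,0,0,0,14.3,TRUE
LBP05,13,12,3,9,1,13.1,FALSE
LBP06,5,5,0,5,0,18.5,FALSE
LBP07,7,5,1,4,2,18.3,FALSE
LBP08,15,4,1,3,11,15.2,FALSE
LBP09,7,6,4,2,1,19.5,FALSE
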