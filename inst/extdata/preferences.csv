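user_id,first_name,bct_action_planning,bct_reward,bct_social_comparison,bct_consequences,bct_barrier_identification,bct_social_support,bct_social_approval,bct_goal_setting,bct_self_monitoring,bct_review_goals
u001,Anna,-1,0,0,1,1,0,-1,1,1,0
u002,Bram,1,1,-1,1,1,1,0,0,-1,-1
u003,Carla,0,-1,0,0,0,0,-1,1,1,0
u004,Daan,0,0,-1,0,0,0,0,-1,1,1
u005,Els,1,1,0,0,1,1,1,1,0,0
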